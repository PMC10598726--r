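#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Affine-invariant ensemble sampler (stretch move) with the model's
// log-posterior evaluated in compiled code. Parameters are sampled on the
// log scale (component order rho, K, N_initial, alpha_RT) with truncated
// normal priors on the natural scale and the log-transform Jacobian.
//
// Uses R's RNG so runs are reproducible under set.seed().

struct Posterior {
  // priors: 4 x 4 matrix rows = (mu, sigma, lower, upper), cols = parameters
  NumericMatrix priors;
  std::vector<int> event_step;   // integration step index of each event
  std::vector<double> event_dose;
  std::vector<bool> event_chemo;
  std::vector<int> obs_step;     // step index of each likelihood observation
  std::vector<double> obs_value;
  double sigma, S_C, ab_ratio, dt;
  int nsteps;

  double log_post(const double* x) const {
    double th[4];
    for (int k = 0; k < 4; ++k) {
      th[k] = std::exp(x[k]);
      if (th[k] < priors(2, k) || th[k] > priors(3, k)) return R_NegInf;
    }
    if (th[2] >= th[1]) return R_NegInf;  // N_initial below K
    const double rho = th[0], K = th[1], alpha = th[3];
    double N = th[2];
    double lp = 0.0;
    size_t e = 0, o = 0;
    for (int j = 0; j <= nsteps && o < obs_step.size(); ++j) {
      if ((int) obs_step[o] == j) {   // pre-event state at this grid time
        lp += R::dnorm(obs_value[o], N, sigma, 1) -
              R::pnorm(0.0, N, sigma, 0, 1);
        ++o;
        if (o >= obs_step.size()) break;
      }
      if (j == nsteps) break;
      if (e < event_step.size() && event_step[e] == j) {
        double s = event_chemo[e] ? S_C : 1.0;
        double d = event_dose[e];
        if (d > 0.0) s *= std::exp(-alpha * d - (alpha / ab_ratio) * d * d);
        N *= s;
        ++e;
      }
      N += dt * rho * N * (1.0 - N / K);
      if (N < 0.0) N = 0.0;
      if (!std::isfinite(N)) return R_NegInf;
    }
    for (int k = 0; k < 4; ++k) {
      double z = R::pnorm(priors(3, k), priors(0, k), priors(1, k), 1, 0) -
                 R::pnorm(priors(2, k), priors(0, k), priors(1, k), 1, 0);
      lp += R::dnorm(th[k], priors(0, k), priors(1, k), 1) - std::log(z);
      lp += x[k];  // Jacobian of the log transform
    }
    return lp;
  }
};

// [[Rcpp::export(name = ".log_post_cpp")]]
double log_post_cpp(NumericVector x, NumericMatrix priors,
                    IntegerVector event_step, NumericVector event_dose,
                    LogicalVector event_chemo, IntegerVector obs_step,
                    NumericVector obs_value, double sigma, double S_C,
                    double ab_ratio, double dt, int nsteps) {
  Posterior p;
  p.priors = priors;
  p.event_step = as<std::vector<int> >(event_step);
  p.event_dose = as<std::vector<double> >(event_dose);
  p.event_chemo = as<std::vector<bool> >(event_chemo);
  p.obs_step = as<std::vector<int> >(obs_step);
  p.obs_value = as<std::vector<double> >(obs_value);
  p.sigma = sigma; p.S_C = S_C; p.ab_ratio = ab_ratio; p.dt = dt;
  p.nsteps = nsteps;
  return p.log_post(REAL(x));
}

// [[Rcpp::export(name = ".stretch_sampler_cpp")]]
List stretch_sampler_cpp(NumericVector x_center, int warm_steps,
                         int samp_steps, int thin, int n_walkers, double a,
                         NumericMatrix priors, IntegerVector event_step,
                         NumericVector event_dose, LogicalVector event_chemo,
                         IntegerVector obs_step, NumericVector obs_value,
                         double sigma, double S_C, double ab_ratio,
                         double dt, int nsteps) {
  Posterior p;
  p.priors = priors;
  p.event_step = as<std::vector<int> >(event_step);
  p.event_dose = as<std::vector<double> >(event_dose);
  p.event_chemo = as<std::vector<bool> >(event_chemo);
  p.obs_step = as<std::vector<int> >(obs_step);
  p.obs_value = as<std::vector<double> >(obs_value);
  p.sigma = sigma; p.S_C = S_C; p.ab_ratio = ab_ratio; p.dt = dt;
  p.nsteps = nsteps;

  const int d = x_center.size();
  RNGScope scope;

  std::vector<std::vector<double> > walkers(n_walkers,
                                            std::vector<double>(d));
  std::vector<double> lp(n_walkers);
  const double init_scales[4] = {0.05, 0.01, 0.002, 0.0};
  for (int w = 0; w < n_walkers; ++w) {
    double l = R_NegInf;
    for (int s = 0; s < 4 && !std::isfinite(l); ++s) {
      for (int k = 0; k < d; ++k)
        walkers[w][k] = x_center[k] + init_scales[s] * norm_rand();
      l = p.log_post(walkers[w].data());
    }
    if (!std::isfinite(l))
      stop("could not initialize walker at a finite log-posterior value");
    lp[w] = l;
  }

  NumericMatrix out(samp_steps * n_walkers, d);
  std::vector<double> prop(d);
  long n_acc = 0, n_prop = 0;
  int kept = 0;
  const int total_steps = warm_steps + samp_steps * thin;
  for (int step = 1; step <= total_steps; ++step) {
    for (int w = 0; w < n_walkers; ++w) {
      int j = (int) (unif_rand() * (n_walkers - 1));
      if (j >= w) ++j;
      double z = (a - 1.0) * unif_rand() + 1.0;
      z = z * z / a;
      for (int k = 0; k < d; ++k)
        prop[k] = walkers[j][k] + z * (walkers[w][k] - walkers[j][k]);
      double lp_prop = p.log_post(prop.data());
      double log_acc = (d - 1) * std::log(z) + lp_prop - lp[w];
      if (std::isfinite(lp_prop) && std::log(unif_rand()) < log_acc) {
        walkers[w] = prop;
        lp[w] = lp_prop;
        if (step > warm_steps) ++n_acc;
      }
      if (step > warm_steps) ++n_prop;
    }
    if (step > warm_steps && (step - warm_steps) % thin == 0) {
      for (int w = 0; w < n_walkers; ++w)
        for (int k = 0; k < d; ++k)
          out(kept * n_walkers + w, k) = walkers[w][k];
      ++kept;
    }
  }
  return List::create(_["draws"] = out,
                      _["accept_rate"] = (double) n_acc / (double) n_prop);
}
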