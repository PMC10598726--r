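# gliotwin

Predictive digital twins for risk-aware radiotherapy (RT) planning in
high-grade glioma.

Response to the standard-of-care RT schedule for high-grade glioma — 30
fractions of 2 Gy over six weeks (60 Gy) with concomitant chemotherapy — is
highly heterogeneous across patients, yet every patient receives the same
schedule. `gliotwin` builds a per-patient *digital twin*: a mechanistic
tumor-growth model with uncertain, patient-specific parameters that is
calibrated to that patient's sparse, noisy tumor-burden measurements and
then used to optimize the weekly RT dose schedule under uncertainty. The
package is aimed at computational-oncology and uncertainty-quantification
researchers; it runs entirely on an in-silico patient cohort (no clinical
data are required or included).

## The model and method in brief

* **Forward model.** Logistic tumor growth
  `dN/dt = rho * N * (1 - N/K)`, integrated by forward Euler (dt = 0.2
  days, 152-day horizon), with instantaneous treatment events: each
  treatment day multiplies the cell count by the linear-quadratic surviving
  fraction `S_C * exp(-alpha_RT * d - beta_RT * d^2)` (`beta_RT =
  alpha_RT/10`, chemotherapy factor `S_C = 0.82`).
* **Digital state.** `theta = (rho, K, N_initial, alpha_RT)` with
  literature-informed truncated normal priors.
* **Calibration.** Two-step Bayesian update from observations on days 0,
  20 and 27 (noise sd `sigma = 2e9` cells): the day-0 scan pins the initial
  burden; an affine-invariant ensemble MCMC sampler then draws the joint
  posterior, gated on split-Rhat < 1.01.
* **Risk.** Tumor control is the time to progression (TTP, capped at 132
  days), summarized per patient by the alpha-superquantile (CVaR,
  `alpha = 0.95`) — the mean of the worst 5% of Monte-Carlo outcomes.
* **Optimization.** Weekly doses of RT weeks 2–6 (week 1 fixed at 2
  Gy/day) minimize the superquantile risk plus a small dose penalty
  (`lambda = 0.001`) subject to `5*||u||_1 <= D_max`; sweeping `D_max` over
  {40, 50, 60, 70, 80, 100} Gy traces the Pareto front between tumor
  control and total dose.
* **Cohort analysis.** Kaplan-Meier curves over per-patient TTP
  superquantiles with right-censoring at 132 days, logrank comparison
  against the standard of care, progressor stratification, and the
  achievable dose reduction at matched tumor control.

See the methods vignette (`vignettes/digital-twin-methods.Rmd`) for the full
account, including the numerical conventions and known limitations.

## Worked example

Calibrate a digital twin for one virtual patient and optimize their
schedule at the standard-of-care total dose:

```r
library(gliotwin)

# ground truth for the virtual patient (hidden from the twin)
truth <- tumor_parameters(rho = 0.109, K = 1.09e11,
                          N_initial = 2.6e10, alpha_RT = 0.0458)
obs <- generate_observations(truth, seed = 42)

post <- calibrate(obs, settings = mcmc_settings(
  chains = 4, draws_per_chain = 5000, retained = 5000,
  warmup = 20000, thin = 24, seed = 42))
print(post)
#> Posterior samples: 5000 retained draws, mean acceptance 0.53
#>                mean        sd  rhat   ess
#> rho       1.211e-01 2.125e-02 1.001 19847
#> K         1.057e+11 1.229e+10 1.001 19701
#> N_initial 2.878e+10 1.750e+09 1.001 20000
#> alpha_RT  5.755e-02 1.175e-02 1.001 20000

ttp_superquantile(post, soc_regimen(), risk_spec(0.95), n_MC = 1000, seed = 1)
#> [1] 98.204

optimize_regimen(post, D_max = 60, settings = ouu_settings(
  restarts = 5, max_evals_per_restart = 100, n_MC = 1000, seed = 1))
#> Optimal regimen at D_max = 60 Gy (alpha = 0.95):
#>   u* = 2.000, 1.169, 0.538, 2.467, 4.957, 0.771 Gy/day
#>   total dose 59.51 Gy; TTP superquantile 100.9 days (457 evals)
```

The posterior concentrates near the (unseen) truth and sharpens every prior.
Under the standard of care this patient's conservative tumor-control summary
is a TTP superquantile of 98.2 days; redistributing the same total dose
toward the middle and late treatment weeks raises it to 100.9 days — extra
days of tumor control at identical total dose, the characteristic gain of
personalized scheduling.

The full cohort experiment (generate patients, calibrate, optimize, analyze
survival) is one call:

```r
report <- run_experiment(experiment_config(n_p = 100, seed = 1))
compare_to_soc(report)
```

or, from a shell, the staged CLI:

```sh
Rscript inst/scripts/gliotwin.R simulate-cohort --config cfg.yml --outdir out
Rscript inst/scripts/gliotwin.R calibrate       --config cfg.yml --outdir out
Rscript inst/scripts/gliotwin.R optimize        --config cfg.yml --outdir out
Rscript inst/scripts/gliotwin.R report          --config cfg.yml --outdir out
```

Stages persist per-patient artifacts (records, posterior draws, Pareto
tables) in `--outdir` and are resumable; reruns with the same configuration
reuse them.

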