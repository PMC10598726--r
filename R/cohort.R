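#' Truncated normal specification
#'
#' Parameters of a truncated normal distribution TN(mu, sigma^2, lower,
#' upper): mean and standard deviation of the parent normal plus truncation
#' bounds.
#'
#' @param mu Mean of the parent normal.
#' @param sigma Standard deviation of the parent normal, > 0.
#' @param lower,upper Truncation bounds, `lower < upper` (`upper` may be
#'   `Inf`).
#' @return An object of class `truncnorm_spec`.
#' @export
truncnorm_spec <- function(mu, sigma, lower = -Inf, upper = Inf) {
  stopifnot(
    "sigma must be positive" = is.numeric(sigma) && sigma > 0,
    "lower must be below upper" = lower < upper
  )
  structure(list(mu = mu, sigma = sigma, lower = lower, upper = upper),
            class = "truncnorm_spec")
}

#' @export
print.truncnorm_spec <- function(x, ...) {
  cat(sprintf("TN(mu = %.4g, sigma = %.4g, [%.4g, %.4g])\n",
              x$mu, x$sigma, x$lower, x$upper))
  invisible(x)
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampling: uniforms are drawn on the CDF interval of the
#' truncation bounds and mapped through the normal quantile function, so all
#' draws respect the bounds exactly.
#'
#' @param spec A [truncnorm_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed (set before drawing when supplied).
#' @return Numeric vector of `n` draws within `[lower, upper]`.
#' @export
sample_truncated_normal <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "truncnorm_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  plo <- stats::pnorm(spec$lower, spec$mu, spec$sigma)
  phi <- stats::pnorm(spec$upper, spec$mu, spec$sigma)
  if (phi - plo < .Machine$double.xmin)
    stop("degenerate truncation: the bounds carry no probability mass")
  x <- stats::qnorm(stats::runif(n, plo, phi), spec$mu, spec$sigma)
  pmin(pmax(x, spec$lower), spec$upper)
}

#' Truncated normal log-density
#'
#' @param x Evaluation points.
#' @param spec A [truncnorm_spec()].
#' @return Log-density values (`-Inf` outside the truncation bounds).
#' @export
dtruncnorm_log <- function(x, spec) {
  z <- stats::pnorm(spec$upper, spec$mu, spec$sigma) -
    stats::pnorm(spec$lower, spec$mu, spec$sigma)
  out <- stats::dnorm(x, spec$mu, spec$sigma, log = TRUE) - log(z)
  out[x < spec$lower | x > spec$upper] <- -Inf
  out
}

#' Mean of a truncated normal distribution
#'
#' Closed form `mu + sigma * (phi(a) - phi(b)) / (Phi(b) - Phi(a))` with
#' standardized bounds a, b.
#'
#' @param spec A [truncnorm_spec()].
#' @return The distribution mean.
#' @export
truncnorm_mean <- function(spec) {
  a <- (spec$lower - spec$mu) / spec$sigma
  b <- (spec$upper - spec$mu) / spec$sigma
  spec$mu + spec$sigma * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Population-level prior for the tumor parameters
#'
#' Independent truncated normal priors for rho, K, N_initial and alpha_RT,
#' informed by literature values for high-grade glioma growth and
#' radiotherapy response.
#'
#' @param rho,K,N_initial,alpha_RT [truncnorm_spec()] objects; defaults are
#'   the literature-informed values (e.g. rho: mean 0.09/day, sd 0.15,
#'   bounds \[0.007, 0.25\]).
#' @return An object of class `prior_spec`: named list of the four specs.
#' @export
default_prior <- function(rho = truncnorm_spec(0.09, 0.15, 0.007, 0.25),
                          K = truncnorm_spec(1e11, 2e10, 9e10, 1.8e11),
                          N_initial = truncnorm_spec(1.9e10, 1.2e10, 4.7e9, 4.7e10),
                          alpha_RT = truncnorm_spec(0.05, 0.025, 0.001, 0.1)) {
  prior <- list(rho = rho, K = K, N_initial = N_initial, alpha_RT = alpha_RT)
  stopifnot(all(vapply(prior, inherits, logical(1), "truncnorm_spec")))
  if (any(vapply(prior, function(s) s$lower, numeric(1)) <= 0))
    stop("all prior lower bounds must be strictly positive")
  structure(prior, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Parameter priors (independent truncated normals):\n")
  for (nm in names(x))
    cat(sprintf("  %-10s TN(%.4g, %.4g, [%.4g, %.4g])\n", nm,
                x[[nm]]$mu, x[[nm]]$sigma, x[[nm]]$lower, x[[nm]]$upper))
  invisible(x)
}

#' Sample an in-silico patient cohort
#'
#' Draws ground-truth parameter sets independently from the marginal priors.
#' Each patient uses a derived random substream (`seed + patient index`) so a
#' cohort can be extended without perturbing existing patients.
#'
#' @param prior A `prior_spec` from [default_prior()].
#' @param n_p Number of patients, >= 1.
#' @param seed Integer master seed.
#' @return List of `n_p` [tumor_parameters()] objects.
#' @export
sample_cohort <- function(prior = default_prior(), n_p, seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"), n_p >= 1)
  lapply(seq_len(n_p), function(i) {
    set.seed(patient_seed(seed, i, stage = 0L))
    vals <- vapply(prior, function(s) sample_truncated_normal(s, 1), numeric(1))
    tumor_parameters(vals[["rho"]], vals[["K"]], vals[["N_initial"]],
                     vals[["alpha_RT"]])
  })
}

# Derived substream seed for (patient, stage); stays below 2^31.
patient_seed <- function(seed, patient, stage = 0L) {
  as.integer((as.numeric(seed) + 99991 * patient + 7919 * stage) %% 2147483647)
}

#' Noisy tumor-burden observations
#'
#' Container for scalar tumor-cell-count measurements (MRI-derived in the
#' clinical setting) with their acquisition days and the known noise scale.
#'
#' @param times Observation days, strictly increasing.
#' @param values Observed cell counts, >= 0.
#' @param sigma Noise standard deviation (cells); default 2e9, i.e. 10% of
#'   the prior mean initial burden.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(times, values, sigma = 2e9) {
  stopifnot(
    length(times) == length(values),
    "observation times must be strictly increasing" = all(diff(times) > 0),
    "observed cell counts must be nonnegative" = all(values >= 0),
    "sigma must be positive" = sigma > 0
  )
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 sigma = sigma),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Tumor-burden observations (sigma =", format(x$sigma), "cells):\n")
  print(data.frame(day = x$times, cells = x$values))
  invisible(x)
}

#' Generate noisy observations for an in-silico patient
#'
#' Simulates the true trajectory under the given regimen and adds truncated
#' normal noise TN(0, sigma^2, -N(t_i), +Inf), so observations are never
#' negative.
#'
#' @param theta_true Ground-truth [tumor_parameters()] (hidden from
#'   calibration).
#' @param regimen [treatment_regimen()] under which the data are acquired
#'   (the standard of care during RT week 1 for the default day-27 scan).
#' @param times Observation days; must lie on the integration grid. Default
#'   `c(0, 20, 27)`: post-surgery, pre-RT, and end of the first RT week.
#' @param sigma Noise sd (cells).
#' @param seed Optional integer seed.
#' @param constants A [fixed_constants()] object.
#' @return An [observation_set()].
#' @export
generate_observations <- function(theta_true, regimen = soc_regimen(),
                                  times = c(0, 20, 27), sigma = 2e9,
                                  seed = NULL, constants = fixed_constants()) {
  stopifnot(all(times >= 0), all(times <= constants$t_finite))
  if (!is.null(seed)) set.seed(seed)
  tr <- simulate_trajectory(theta_true, treatment_events(regimen, constants),
                            constants, t_end = max(times))
  mu <- tr$cells[grid_index(times, constants)]
  eps <- vapply(mu, function(m)
    sample_truncated_normal(truncnorm_spec(0, sigma, lower = -m), 1),
    numeric(1))
  observation_set(times, mu + eps, sigma)
}

#' Serialize a patient record to JSON
#'
#' The ground truth is stored under a `theta_true_hidden` block: it is
#' available for truth-vs-posterior diagnostics but is never read by the
#' calibration or optimization code paths.
#'
#' @param patient_id Identifier.
#' @param theta_true [tumor_parameters()] ground truth.
#' @param obs [observation_set()].
#' @param seed Seed used for this patient.
#' @param file Optional path; when given the JSON is written there.
#' @return JSON string (invisibly if `file` given).
#' @export
patient_record_json <- function(patient_id, theta_true, obs, seed,
                                file = NULL) {
  rec <- list(
    patient_id = patient_id,
    theta_true_hidden = unclass(theta_true),
    observations = list(times = obs$times, values = obs$values,
                        sigma = obs$sigma),
    seed = seed
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
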