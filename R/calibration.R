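#' MCMC sampler settings
#'
#' @param chains Number of chains (>= 2, for split-Rhat).
#' @param draws_per_chain Post-warmup draws kept per chain.
#' @param retained Total number of retained draws after combining chains
#'   (evenly thinned); must not exceed `chains * draws_per_chain`.
#' @param warmup Warmup draws per chain (discarded while the walker ensemble
#'   equilibrates). Default four times `draws_per_chain`, at least 10000.
#' @param thin Ensemble steps between retained snapshots (>= 1). Thinning
#'   buys decorrelation along the weakly identified rho-K posterior ridge at
#'   linear cost.
#' @param seed Integer seed.
#' @param convergence_threshold Split-Rhat limit above which [calibrate()]
#'   fails with a diagnostic error.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, draws_per_chain = 100000,
                          retained = 100000,
                          warmup = max(10000, 4 * draws_per_chain),
                          thin = 1L, seed = 1L,
                          convergence_threshold = 1.01) {
  stopifnot(
    "at least two chains are required" = chains >= 2,
    draws_per_chain >= 10,
    "retained must not exceed chains * draws_per_chain" =
      retained <= chains * draws_per_chain,
    warmup >= 0, thin >= 1, convergence_threshold > 1
  )
  structure(list(chains = as.integer(chains),
                 draws_per_chain = as.integer(draws_per_chain),
                 retained = as.integer(retained), warmup = as.integer(warmup),
                 thin = as.integer(thin), seed = as.integer(seed),
                 convergence_threshold = convergence_threshold),
            class = "mcmc_settings")
}

#' Step-1 update of the initial tumor burden
#'
#' The post-surgery (day-0) observation directly informs the initial burden:
#' its posterior is TN(o, sigma^2, max(0, o - 2*sigma), o + 2*sigma), which
#' replaces the population prior on `N_initial` in the MCMC step.
#'
#' @param o_t1 Day-0 observed cell count, >= 0.
#' @param sigma Observation noise sd (cells).
#' @return A [truncnorm_spec()].
#' @examples
#' initial_burden_update(1.9e10, 2e9)  # TN(1.9e10, (2e9)^2, 1.5e10, 2.3e10)
#' @export
initial_burden_update <- function(o_t1, sigma) {
  stopifnot(o_t1 >= 0, sigma > 0)
  truncnorm_spec(o_t1, sigma, max(0, o_t1 - 2 * sigma), o_t1 + 2 * sigma)
}

#' Observation log-likelihood
#'
#' Sum over observations of the truncated normal log-density of the observed
#' count given model mean `N(t_i; theta, u)` and sd `sigma`, truncated to
#' nonnegative observations (matching the generative noise model). The day-0
#' observation is expected to be excluded by the caller (it defines the
#' Step-1 prior on `N_initial`).
#'
#' @param theta A [tumor_parameters()] object.
#' @param obs An [observation_set()].
#' @param regimen A [treatment_regimen()].
#' @param constants A [fixed_constants()] object.
#' @return Scalar log-likelihood; `-Inf` if the model output is non-finite.
#' @export
log_likelihood <- function(theta, obs, regimen = soc_regimen(),
                           constants = fixed_constants()) {
  events <- treatment_events(regimen, constants)
  tr <- tryCatch(
    simulate_trajectory(theta, events, constants, t_end = max(obs$times)),
    error = function(e) NULL)
  if (is.null(tr)) return(-Inf)
  mu <- tr$cells[grid_index(obs$times, constants)]
  if (any(!is.finite(mu))) return(-Inf)
  sum(obs_log_density(obs$values, mu, obs$sigma))
}

# log-density of o given mean mu, sd sigma, support o >= 0
# (observation = mu + eps, eps ~ TN(0, sigma^2, -mu, Inf))
obs_log_density <- function(o, mu, sigma) {
  stats::dnorm(o, mu, sigma, log = TRUE) -
    stats::pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
}

#' Calibrate a patient's digital twin
#'
#' Two-step Bayesian assimilation. Step 1 converts the day-0 observation into
#' a truncated normal prior on the initial burden ([initial_burden_update()]).
#' Step 2 samples the joint posterior of (rho, K, N_initial, alpha_RT) by
#' adaptive random-walk Metropolis on log-transformed parameters (with
#' Jacobian correction), using the remaining observations in the likelihood.
#' Convergence is checked with split-Rhat; the run fails loudly if any
#' parameter exceeds the threshold.
#'
#' @param obs [observation_set()] containing the day-0 observation plus at
#'   least one observation after the start of RT (needed to inform
#'   `alpha_RT`).
#' @param prior `prior_spec` from [default_prior()].
#' @param regimen [treatment_regimen()] delivered while the data were
#'   acquired.
#' @param settings [mcmc_settings()].
#' @param constants [fixed_constants()].
#' @return An object of class `posterior_samples`: list with `draws`
#'   (retained x 4 matrix, natural scale), `diagnostics` (data frame with
#'   per-parameter split-Rhat and effective sample size), `accept_rate`,
#'   `n_initial_prior` (the Step-1 spec) and `settings`.
#' @export
calibrate <- function(obs, prior = default_prior(), regimen = soc_regimen(),
                      settings = mcmc_settings(),
                      constants = fixed_constants()) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(settings, "mcmc_settings"))
  if (!any(obs$times == 0))
    stop("calibration requires the day-0 (post-surgery) observation")
  if (!any(obs$times > constants$rt_start_day))
    stop("calibration requires at least one observation after the start of ",
         "RT (day ", constants$rt_start_day, ") to inform alpha_RT")

  # Step 1: initial-burden prior from the day-0 observation
  o0 <- obs$values[obs$times == 0][1]
  n_init_spec <- initial_burden_update(o0, obs$sigma)
  step2_prior <- prior
  step2_prior$N_initial <- n_init_spec

  keep <- obs$times > 0
  obs2 <- observation_set(obs$times[keep], obs$values[keep], obs$sigma)

  events <- treatment_events(regimen, constants)
  events <- events[order(events$day), , drop = FALSE]
  t_end <- max(obs2$times)
  steps_per_day <- as.integer(round(1 / constants$dt))
  nsteps <- as.integer(round(t_end / constants$dt))
  obs_ord <- order(obs2$times)
  par_names <- c("rho", "K", "N_initial", "alpha_RT")
  # rows mu, sigma, lower, upper; columns in parameter order
  prior_mat <- vapply(step2_prior[par_names], function(s)
    c(s$mu, s$sigma, s$lower, s$upper), numeric(4))

  log_post <- function(x)
    .log_post_cpp(x, prior_mat, as.integer(events$day * steps_per_day),
                  as.numeric(events$rt_dose_gy), as.logical(events$chemo),
                  as.integer(round(obs2$times[obs_ord] / constants$dt)),
                  obs2$values[obs_ord], obs2$sigma, constants$S_C,
                  constants$alpha_beta_ratio, constants$dt, nsteps)

  # Posterior-mode search from the prior center; walker ensembles start in a
  # small ball around the mode and expand to the posterior during warmup.
  center <- vapply(step2_prior, function(s) {
    m <- truncnorm_mean(s)
    lo <- s$lower + 0.05 * (min(s$upper, s$lower + 8 * s$sigma) - s$lower)
    max(m, lo)
  }, numeric(1))
  names(center) <- par_names
  map <- stats::optim(log(center), function(x) -log_post(x),
                      method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-10))
  n_walkers <- 32L
  warm_steps <- max(10L, as.integer(ceiling(settings$warmup / n_walkers)))
  samp_steps <- as.integer(ceiling(settings$draws_per_chain / n_walkers))
  chains <- lapply(seq_len(settings$chains), function(c_id) {
    set.seed(patient_seed(settings$seed, c_id, stage = 101L))
    res <- .stretch_sampler_cpp(map$par, warm_steps, samp_steps,
                                settings$thin, n_walkers, 2.0, prior_mat,
                                as.integer(events$day * steps_per_day),
                                as.numeric(events$rt_dose_gy),
                                as.logical(events$chemo),
                                as.integer(round(obs2$times[obs_ord] /
                                                   constants$dt)),
                                obs2$values[obs_ord], obs2$sigma,
                                constants$S_C, constants$alpha_beta_ratio,
                                constants$dt, nsteps)
    res$draws <- res$draws[seq_len(settings$draws_per_chain), ,
                           drop = FALSE]
    res
  })
  draws_by_chain <- lapply(chains, `[[`, "draws")
  accept_rate <- mean(vapply(chains, `[[`, numeric(1), "accept_rate"))

  diag <- mcmc_diagnostics(draws_by_chain, par_names)
  if (any(diag$rhat > settings$convergence_threshold)) {
    msg <- paste0("MCMC did not converge: split-Rhat = ",
                  paste(sprintf("%s %.4f", diag$parameter, diag$rhat),
                        collapse = ", "))
    cond <- structure(class = c("gliotwin_nonconvergence", "error",
                                "condition"),
                      list(message = msg, call = sys.call(-1),
                           diagnostics = diag))
    stop(cond)
  }

  all_draws <- exp(do.call(rbind, draws_by_chain))
  colnames(all_draws) <- par_names
  idx <- unique(round(seq(1, nrow(all_draws), length.out = settings$retained)))
  structure(list(draws = all_draws[idx, , drop = FALSE], diagnostics = diag,
                 accept_rate = accept_rate, n_initial_prior = n_init_spec,
                 settings = settings),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: %d retained draws, mean acceptance %.2f\n",
              nrow(x$draws), x$accept_rate))
  smry <- data.frame(
    mean = colMeans(x$draws),
    sd = apply(x$draws, 2, stats::sd),
    rhat = x$diagnostics$rhat,
    ess = round(x$diagnostics$ess)
  )
  print(format(smry, digits = 4))
  invisible(x)
}

# Split-Rhat and a basic effective-sample-size estimate over chains.
mcmc_diagnostics <- function(draws_by_chain, par_names) {
  half <- function(m) {
    n <- nrow(m) %/% 2
    list(m[seq_len(n), , drop = FALSE],
         m[seq.int(nrow(m) - n + 1, nrow(m)), , drop = FALSE])
  }
  split_chains <- do.call(c, lapply(draws_by_chain, half))
  d <- length(par_names)
  rhat <- ess <- numeric(d)
  for (j in seq_len(d)) {
    cols <- lapply(split_chains, function(m) m[, j])
    n <- length(cols[[1]])
    m <- length(cols)
    means <- vapply(cols, mean, numeric(1))
    vars <- vapply(cols, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    var_plus <- (n - 1) / n * W + B / n
    rhat[j] <- if (W > 0) sqrt(var_plus / W) else 1
    # ESS from averaged autocorrelations (truncated at first negative pair)
    rho_sum <- 0
    max_lag <- min(n - 2, 200)
    acfs <- vapply(cols, function(v)
      stats::acf(v, lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf[-1, 1, 1],
      numeric(max_lag))
    rho <- 1 - (W - rowMeans(acfs * rep(vars, each = max_lag))) /
      ifelse(var_plus > 0, var_plus, 1)
    t <- 1
    while (t < max_lag - 1 && (rho[t] + rho[t + 1]) > 0) {
      rho_sum <- rho_sum + rho[t] + rho[t + 1]
      t <- t + 2
    }
    ess[j] <- m * n / (1 + 2 * rho_sum)
  }
  data.frame(parameter = par_names, rhat = rhat, ess = ess)
}

#' Posterior-predictive trajectory ensemble
#'
#' Propagates posterior parameter uncertainty through the forward model:
#' samples `n` draws from the posterior, simulates each trajectory under the
#' given regimen, and summarizes per-time min/median/max bands.
#'
#' @param posterior A `posterior_samples` object (or any n x 4 draw matrix).
#' @param regimen A [treatment_regimen()].
#' @param n Number of trajectories (<= number of retained draws).
#' @param constants [fixed_constants()].
#' @param seed Optional integer seed for the draw subset.
#' @return List with `times`, `cells` (matrix, one column per draw) and
#'   `bands` (data frame: `time_days`, `min`, `median`, `max`).
#' @export
posterior_predictive <- function(posterior, regimen = soc_regimen(), n = 1000,
                                 constants = fixed_constants(), seed = NULL) {
  draws <- if (inherits(posterior, "posterior_samples")) posterior$draws
           else param_matrix(posterior)
  stopifnot(n >= 1, n <= nrow(draws))
  if (!is.null(seed)) set.seed(seed)
  idx <- if (n == nrow(draws)) seq_len(n) else sample.int(nrow(draws), n)
  cells <- simulate_ensemble(draws[idx, , drop = FALSE], regimen, constants)
  times <- time_grid(constants)
  bands <- data.frame(
    time_days = times,
    min = apply(cells, 1, min),
    median = apply(cells, 1, stats::median),
    max = apply(cells, 1, max)
  )
  list(times = times, cells = cells, bands = bands)
}

#' Export posterior draws as CSV with a JSON diagnostics sidecar
#'
#' @param posterior A `posterior_samples` object.
#' @param file CSV path for the draws (columns rho, K, N_initial, alpha_RT);
#'   diagnostics go to `<file>.diagnostics.json`.
#' @return The CSV path, invisibly.
#' @export
write_posterior_csv <- function(posterior, file) {
  utils::write.csv(as.data.frame(posterior$draws), file, row.names = FALSE)
  jsonlite::write_json(
    list(diagnostics = posterior$diagnostics,
         accept_rate = posterior$accept_rate),
    paste0(file, ".diagnostics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(file)
}
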