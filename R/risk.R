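#' Risk level specification
#'
#' @param alpha Risk level in (0, 1); the superquantile averages the worst
#'   `100*(1-alpha)%` of outcomes. Default 0.95.
#' @return An object of class `risk_spec`.
#' @export
risk_spec <- function(alpha = 0.95) {
  stopifnot("alpha must be in (0, 1)" = alpha > 0 && alpha < 1)
  structure(list(alpha = alpha), class = "risk_spec")
}

#' Time to progression of a single parameter set
#'
#' Progression is the first time after the end of RT at which the tumor
#' burden exceeds its pre-RT value `N_th = N(t = rt_start_day)`. TTP is that
#' time minus `rt_start_day`, capped (right-censored) at
#' `t_finite - rt_start_day` (132 days under the defaults) when the burden
#' never re-exceeds the threshold within the horizon. Detection uses the
#' integration grid, so TTP has resolution `dt`.
#'
#' @param theta A [tumor_parameters()] object.
#' @param regimen A [treatment_regimen()].
#' @param constants A [fixed_constants()] object.
#' @return List with `ttp` (days), `threshold_cells` and `censored`.
#' @examples
#' th <- tumor_parameters(0.007, 1e11, 1.9e10, alpha_RT = 0.1)
#' time_to_progression(th, soc_regimen())$ttp  # 132, censored
#' @export
time_to_progression <- function(theta, regimen = soc_regimen(),
                                constants = fixed_constants()) {
  res <- ttp_ensemble(param_matrix(theta), regimen, constants)
  list(ttp = res$ttp[1], threshold_cells = res$threshold_cells[1],
       censored = res$censored[1])
}

# Vectorized TTP over a parameter draw matrix (rows = draws).
ttp_ensemble <- function(draws, regimen = soc_regimen(),
                         constants = fixed_constants()) {
  m <- param_matrix(draws)
  events <- treatment_events(regimen, constants)
  .ttp_ensemble_cpp(m[, "rho"], m[, "K"], m[, "N_initial"], m[, "alpha_RT"],
                    as.integer(events$day), as.numeric(events$rt_dose_gy),
                    as.logical(events$chemo), constants$S_C,
                    constants$alpha_beta_ratio, constants$dt,
                    constants$t_finite, constants$rt_start_day,
                    constants$t_post_rt)
}

#' Quantity-of-interest samples for tumor control
#'
#' The tumor-control QoI is the negative TTP, `M(u, theta) = -T_TTP(u,
#' theta)`, so that minimizing risk of M maximizes time to progression.
#'
#' @param draws Parameter draws (n x 4 matrix, list of [tumor_parameters()],
#'   or a `posterior_samples` object).
#' @param regimen A [treatment_regimen()].
#' @param constants A [fixed_constants()] object.
#' @return Numeric vector of QoI samples (days, in `[-132, 0)` under the
#'   defaults), order-preserving in the draws.
#' @export
qoi_samples <- function(draws, regimen = soc_regimen(),
                        constants = fixed_constants()) {
  if (inherits(draws, "posterior_samples")) draws <- draws$draws
  -ttp_ensemble(draws, regimen, constants)$ttp
}

#' Empirical quantile (upper order statistic)
#'
#' Returns the `ceiling(alpha * n)`-th order statistic, the plug-in inverse
#' CDF without interpolation. This convention makes the plug-in superquantile
#' equal the mean of the worst `(1-alpha)*n` outcomes exactly when that count
#' is an integer.
#'
#' @param values Nonempty numeric sample.
#' @param alpha Level in (0, 1).
#' @return The empirical alpha-quantile.
#' @export
empirical_quantile <- function(values, alpha) {
  stopifnot("empty sample" = length(values) > 0, alpha > 0, alpha < 1)
  sort(values)[ceiling(alpha * length(values))]
}

#' Empirical alpha-superquantile (conditional value-at-risk)
#'
#' Plug-in estimator `Q_alpha + mean(pmax(values - Q_alpha, 0)) / (1 -
#' alpha)`: the quantile plus the scaled mean excess beyond it. Always at
#' least the quantile; for atomless distributions it is the conditional mean
#' of the worst `100*(1-alpha)%` of outcomes.
#'
#' @param values Nonempty numeric sample.
#' @param alpha Level in (0, 1).
#' @return The empirical alpha-superquantile.
#' @examples
#' superquantile(1:100, 0.95)  # 98, the mean of the top five values
#' @export
superquantile <- function(values, alpha) {
  q <- empirical_quantile(values, alpha)
  q + mean(pmax(values - q, 0)) / (1 - alpha)
}

#' Per-patient conservative TTP summary
#'
#' The alpha-superquantile of the TTP: `-superquantile(-TTP, alpha)` over a
#' Monte-Carlo sample of the posterior. This single scalar (a conservative,
#' tail-aware summary of tumor control) is the per-patient quantity used in
#' all cohort analyses.
#'
#' @param posterior `posterior_samples` object or an n x 4 draw matrix.
#' @param regimen A [treatment_regimen()].
#' @param spec A [risk_spec()].
#' @param n_MC Number of Monte-Carlo draws (default 5000); subsampled without
#'   replacement from the posterior when fewer than the retained draws.
#' @param seed Optional integer seed for the subsample.
#' @param constants A [fixed_constants()] object.
#' @return TTP alpha-superquantile in days (at most 132 under the defaults).
#' @export
ttp_superquantile <- function(posterior, regimen = soc_regimen(),
                              spec = risk_spec(), n_MC = 5000, seed = NULL,
                              constants = fixed_constants()) {
  draws <- posterior_subset(posterior, n_MC, seed)
  -superquantile(qoi_samples(draws, regimen, constants), spec$alpha)
}

#' Export TTP Monte-Carlo samples as CSV
#'
#' One column per evaluated regimen, one row per Monte-Carlo draw — the
#' layout used for downstream histogramming of TTP distributions.
#'
#' @param ttp_samples Named list of equal-length TTP sample vectors (e.g.
#'   `list(SOC = ..., "OUU:60 Gy" = ...)`).
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
write_ttp_samples_csv <- function(ttp_samples, file) {
  stopifnot(length(ttp_samples) > 0,
            length(unique(lengths(ttp_samples))) == 1)
  utils::write.csv(as.data.frame(ttp_samples, check.names = FALSE), file,
                   row.names = FALSE)
  invisible(file)
}

# Freeze a Monte-Carlo subset of posterior draws (common random numbers).
posterior_subset <- function(posterior, n_MC, seed = NULL) {
  draws <- if (inherits(posterior, "posterior_samples")) posterior$draws
           else param_matrix(posterior)
  stopifnot(n_MC >= 1)
  if (n_MC >= nrow(draws)) return(draws)
  if (!is.null(seed)) set.seed(seed)
  draws[sample.int(nrow(draws), n_MC), , drop = FALSE]
}
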