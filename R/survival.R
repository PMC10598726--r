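#' Classify a patient by progression timing under the standard of care
#'
#' Strata are defined on the SOC TTP alpha-superquantile: early progressors
#' reach progression within one month (30 days) of the end of RT (TTP <= 42 +
#' 30 = 72 days), late progressors never progress within the horizon (TTP at
#' the 132-day cap), and the rest are intermediate.
#'
#' @param soc_ttp_superquantile TTP alpha-superquantile under SOC (days);
#'   vectorized.
#' @param cap Censoring cap (days), default 132.
#' @param tol Tolerance for detecting the cap.
#' @return Factor with levels `early`, `intermediate`, `late`.
#' @export
classify_progressor <- function(soc_ttp_superquantile, cap = 132,
                                tol = 1e-6) {
  stopifnot(all(soc_ttp_superquantile > 0),
            all(soc_ttp_superquantile <= cap + tol))
  out <- ifelse(soc_ttp_superquantile >= cap - tol, "late",
                ifelse(soc_ttp_superquantile <= 72, "early", "intermediate"))
  factor(out, levels = c("early", "intermediate", "late"))
}

#' Kaplan-Meier curve over per-patient TTP values
#'
#' Product-limit estimator `P_S(t) = prod_{i: t_i <= t} (1 - d(t_i)/m(t_i))`
#' over the distinct progression times, with values equal to the censor time
#' treated as right-censored (they reduce the at-risk counts but trigger no
#' survival drop).
#'
#' @param ttp_values One TTP (alpha-superquantile) per patient, in
#'   `(0, censor_time]`.
#' @param censor_time Right-censoring time (days), default 132.
#' @return An object of class `survival_curve`: data frame with columns
#'   `time`, `at_risk`, `events`, `survival` (one row per distinct event
#'   time), plus attributes `censor_time` and `n`.
#' @examples
#' km_curve(c(30, 60, 132))$survival  # 2/3 after t = 30, 1/3 after t = 60
#' @export
km_curve <- function(ttp_values, censor_time = 132) {
  stopifnot("empty cohort" = length(ttp_values) > 0,
            all(ttp_values > 0), all(ttp_values <= censor_time))
  event <- ttp_values < censor_time
  times <- sort(unique(ttp_values[event]))
  n <- length(ttp_values)
  surv <- numeric(length(times))
  at_risk <- events <- integer(length(times))
  s <- 1
  for (i in seq_along(times)) {
    at_risk[i] <- sum(ttp_values >= times[i])
    events[i] <- sum(ttp_values == times[i] & event)
    s <- s * (1 - events[i] / at_risk[i])
    surv[i] <- s
  }
  structure(
    data.frame(time = times, at_risk = at_risk, events = events,
               survival = surv),
    censor_time = censor_time, n = n,
    class = c("survival_curve", "data.frame"))
}

#' Evaluate a survival curve at given times
#'
#' @param curve A `survival_curve`.
#' @param t Times (days).
#' @return Survival probabilities (step function, right-continuous).
#' @export
survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$time <= tt)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

#' Two-sample logrank test
#'
#' Standard observed-minus-expected chi-square logrank statistic (1 df) over
#' the pooled distinct event times, with right-censoring at `censor_time`.
#'
#' @param ttp_a,ttp_b Per-patient TTP values for the two cohorts.
#' @param censor_time Right-censoring time (days), default 132.
#' @return List with `statistic`, `p_value`, `observed` and `expected` event
#'   counts for group A.
#' @export
logrank_test <- function(ttp_a, ttp_b, censor_time = 132) {
  stopifnot("both cohorts must be nonempty" =
              length(ttp_a) > 0 && length(ttp_b) > 0)
  all_t <- c(ttp_a, ttp_b)
  grp_a <- c(rep(TRUE, length(ttp_a)), rep(FALSE, length(ttp_b)))
  event <- all_t < censor_time
  times <- sort(unique(all_t[event]))
  if (length(times) == 0) {
    warning("no events in either cohort; logrank test is degenerate")
    return(list(statistic = 0, p_value = 1, observed = 0, expected = 0))
  }
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- all_t >= tt
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & grp_a)
    d_j <- sum(all_t == tt & event)
    d1_j <- sum(all_t == tt & event & grp_a)
    O <- O + d1_j
    E <- E + d_j * n1_j / n_j
    if (n_j > 1)
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  if (V <= 0) {
    warning("zero logrank variance; test is degenerate")
    return(list(statistic = 0, p_value = 1, observed = O, expected = E))
  }
  stat <- (O - E)^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Dose reduction achievable at matched tumor control
#'
#' From a Pareto set, finds the lowest total dose whose TTP superquantile is
#' within `tolerance` of (or better than) the SOC value, and reports the
#' reduction relative to the 60 Gy SOC total dose. Returns 0 when no
#' solution below 60 Gy qualifies.
#'
#' @param pareto A `pareto_set` from [pareto_sweep()] (or a list of
#'   `optimal_regimen` objects).
#' @param soc_ttp_superquantile The patient's SOC TTP superquantile (days).
#' @param tolerance Matching tolerance (days), default 1.
#' @param soc_dose SOC total dose (Gy), default 60.
#' @return Dose reduction in Gy (>= 0).
#' @export
dose_reduction_analysis <- function(pareto, soc_ttp_superquantile,
                                    tolerance = 1, soc_dose = 60) {
  ttp <- vapply(pareto, `[[`, numeric(1), "ttp_superquantile")
  dose <- vapply(pareto, `[[`, numeric(1), "total_dose")
  ok <- ttp >= soc_ttp_superquantile - tolerance
  if (!any(ok)) return(0)
  max(0, soc_dose - min(dose[ok]))
}

#' Bootstrap variance of the cohort survival curve
#'
#' Resamples each patient's TTP Monte-Carlo draws with replacement,
#' recomputes the per-patient TTP superquantile and the cohort Kaplan-Meier
#' curve, and returns the pointwise variance of the survival probability over
#' bootstrap replicates — a sample-based alternative to Greenwood-type
#' approximations.
#'
#' @param ttp_sample_sets List (one element per patient) of TTP Monte-Carlo
#'   sample vectors.
#' @param n_boot Number of bootstrap replicates.
#' @param alpha Risk level of the superquantile summary.
#' @param times Evaluation time grid (days); default `0:132`.
#' @param censor_time Censoring cap (days).
#' @param seed Optional integer seed.
#' @return List with `times` and `variance` (pointwise survival variance).
#' @export
survival_variance_bootstrap <- function(ttp_sample_sets, n_boot = 200,
                                        alpha = 0.95, times = 0:132,
                                        censor_time = 132, seed = NULL) {
  stopifnot(length(ttp_sample_sets) > 0,
            all(lengths(ttp_sample_sets) > 0), n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  surv <- matrix(NA_real_, n_boot, length(times))
  for (b in seq_len(n_boot)) {
    sq <- vapply(ttp_sample_sets, function(x)
      -superquantile(-sample(x, length(x), replace = TRUE), alpha),
      numeric(1))
    sq <- pmin(pmax(sq, .Machine$double.eps), censor_time)
    surv[b, ] <- survival_at(km_curve(sq, censor_time), times)
  }
  variance <- apply(surv, 2, stats::var)
  if (n_boot == 1) variance <- rep(0, length(times))
  list(times = times, variance = variance)
}

#' Export a survival curve as CSV
#'
#' @param curve A `survival_curve`.
#' @param file CSV path (columns time, at_risk, events, survival and
#'   optionally variance).
#' @param variance Optional pointwise variance at the curve's event times.
#' @return The path, invisibly.
#' @export
write_survival_csv <- function(curve, file, variance = NULL) {
  df <- as.data.frame(curve)
  if (!is.null(variance)) df$variance <- variance
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
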