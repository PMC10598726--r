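#' Patient-specific tumor model parameters
#'
#' The uncertain digital state of one patient: net proliferation rate,
#' carrying capacity, initial tumor burden, and radiosensitivity.
#'
#' @param rho Net proliferation rate (day^-1), > 0.
#' @param K Carrying capacity (cells), > 0.
#' @param N_initial Initial tumor burden (cells), in (0, K).
#' @param alpha_RT Radiosensitivity of the linear-quadratic model (Gy^-1), > 0.
#'
#' @return An object of class `tumor_parameters`.
#' @examples
#' tumor_parameters(rho = 0.09, K = 1e11, N_initial = 1.9e10, alpha_RT = 0.05)
#' @export
tumor_parameters <- function(rho, K, N_initial, alpha_RT) {
  stopifnot(
    "rho must be strictly positive" = is.numeric(rho) && rho > 0,
    "K must be strictly positive" = is.numeric(K) && K > 0,
    "N_initial must be strictly positive" = is.numeric(N_initial) && N_initial > 0,
    "alpha_RT must be strictly positive" = is.numeric(alpha_RT) && alpha_RT > 0,
    "N_initial must be below the carrying capacity K" = N_initial < K
  )
  structure(list(rho = rho, K = K, N_initial = N_initial, alpha_RT = alpha_RT),
            class = "tumor_parameters")
}

#' @export
print.tumor_parameters <- function(x, ...) {
  cat(sprintf(
    "Tumor parameters: rho = %.4g /day, K = %.4g cells, N_initial = %.4g cells, alpha_RT = %.4g /Gy\n",
    x$rho, x$K, x$N_initial, x$alpha_RT))
  invisible(x)
}

# Coerce tumor_parameters / matrix / data.frame to an n x 4 parameter matrix
# with columns rho, K, N_initial, alpha_RT.
param_matrix <- function(theta) {
  cols <- c("rho", "K", "N_initial", "alpha_RT")
  if (inherits(theta, "tumor_parameters"))
    return(matrix(unlist(theta[cols]), nrow = 1,
                  dimnames = list(NULL, cols)))
  if (is.list(theta) && !is.data.frame(theta) &&
      all(vapply(theta, inherits, logical(1), "tumor_parameters")))
    return(do.call(rbind, lapply(theta, param_matrix)))
  m <- as.matrix(as.data.frame(theta))
  if (!all(cols %in% colnames(m)))
    stop("parameter set must have columns ", paste(cols, collapse = ", "))
  m[, cols, drop = FALSE]
}

#' Weekly radiotherapy dose schedule
#'
#' A regimen is a vector of daily RT doses, one entry per treatment week; the
#' dose is delivered on each of the week's fraction days. The standard of
#' care is 2 Gy/day for six weeks (60 Gy total).
#'
#' @param weekly_doses Numeric vector of daily doses (Gy/day), one per RT
#'   week, each in \[0, 10\].
#' @param constants A [fixed_constants()] object; its `weeks` field must match
#'   `length(weekly_doses)`.
#'
#' @return An object of class `treatment_regimen`.
#' @seealso [soc_regimen()], [expand_regimen()]
#' @export
treatment_regimen <- function(weekly_doses, constants = fixed_constants()) {
  stopifnot(is.numeric(weekly_doses), all(is.finite(weekly_doses)))
  if (length(weekly_doses) != constants$weeks)
    stop("regimen must have one dose per RT week (expected ",
         constants$weeks, ", got ", length(weekly_doses), ")")
  if (any(weekly_doses < 0 | weekly_doses > 10))
    stop("weekly doses must lie in [0, 10] Gy/day")
  structure(list(weekly_doses = as.numeric(weekly_doses)),
            class = "treatment_regimen")
}

#' Standard-of-care regimen
#'
#' The Stupp-protocol schedule in weekly form: 2 Gy/day in each of the six RT
#' weeks, i.e. 30 fractions of 2 Gy, 60 Gy total, with concomitant
#' chemotherapy.
#'
#' @param constants A [fixed_constants()] object.
#' @return A [treatment_regimen()] with all weekly doses equal to 2.
#' @export
soc_regimen <- function(constants = fixed_constants()) {
  treatment_regimen(rep(2, constants$weeks), constants)
}

#' Total delivered radiation dose of a regimen
#'
#' @param regimen A [treatment_regimen()].
#' @param constants A [fixed_constants()] object.
#' @return Total dose in Gy: `fractions_per_week * sum(weekly_doses)`.
#' @export
total_dose <- function(regimen, constants = fixed_constants()) {
  constants$fractions_per_week * sum(regimen$weekly_doses)
}

#' @export
print.treatment_regimen <- function(x, ...) {
  cat("RT regimen (Gy/day per week):",
      paste(format(x$weekly_doses, digits = 4), collapse = ", "), "\n")
  cat("  total dose:", format(5 * sum(x$weekly_doses)), "Gy\n")
  invisible(x)
}

#' Expand a weekly regimen into dated daily treatment events
#'
#' Week i occupies the first `fractions_per_week` days of the 7-day window
#' starting at `rt_start_day + 7*(i-1)`. Chemotherapy is administered on every
#' event day of all weeks, including weeks with zero RT dose.
#'
#' @param regimen A [treatment_regimen()].
#' @param constants A [fixed_constants()] object.
#' @return A data frame with columns `day` (integer), `rt_dose_gy`, `chemo`
#'   (logical), one row per treatment day.
#' @examples
#' ev <- expand_regimen(soc_regimen())
#' nrow(ev)            # 30 fractions
#' sum(ev$rt_dose_gy)  # 60 Gy
#' @export
expand_regimen <- function(regimen, constants = fixed_constants()) {
  stopifnot(inherits(regimen, "treatment_regimen"))
  if (length(regimen$weekly_doses) != constants$weeks)
    stop("regimen length does not match constants$weeks")
  week <- rep(seq_len(constants$weeks), each = constants$fractions_per_week)
  offset <- rep(seq_len(constants$fractions_per_week) - 1L, constants$weeks)
  data.frame(
    day = as.integer(constants$rt_start_day + 7L * (week - 1L) + offset),
    rt_dose_gy = regimen$weekly_doses[week],
    chemo = TRUE
  )
}

#' Full treatment-event schedule of a regimen
#'
#' The complete event table the simulation uses: the RT fractions from
#' [expand_regimen()] plus chemotherapy-only days (zero RT dose) on the
#' remaining chemotherapy days of each RT week. Under the defaults
#' chemotherapy is administered daily throughout the six treatment weeks, so
#' the SOC expands to 42 events of which 30 carry an RT fraction.
#'
#' @param regimen A [treatment_regimen()].
#' @param constants A [fixed_constants()] object.
#' @return A data frame with columns `day`, `rt_dose_gy`, `chemo`, ordered
#'   by day.
#' @seealso [expand_regimen()] for the RT fractions alone.
#' @export
treatment_events <- function(regimen, constants = fixed_constants()) {
  ev <- expand_regimen(regimen, constants)
  extra_days <- constants$chemo_days_per_week - constants$fractions_per_week
  if (extra_days > 0) {
    week <- rep(seq_len(constants$weeks), each = extra_days)
    offset <- rep(constants$fractions_per_week +
                    seq_len(extra_days) - 1L, constants$weeks)
    ev <- rbind(ev, data.frame(
      day = as.integer(constants$rt_start_day + 7L * (week - 1L) + offset),
      rt_dose_gy = 0, chemo = TRUE))
  }
  ev[order(ev$day), , drop = FALSE]
}

#' Surviving fraction of a combined RT/chemotherapy dose
#'
#' Linear-quadratic cell survival `exp(-alpha*d - beta*d^2)` with
#' `beta = alpha / alpha_beta_ratio`, multiplied by the chemotherapy surviving
#' fraction `S_C` when chemotherapy is given.
#'
#' @param rt_dose RT dose of the fraction (Gy, >= 0); vectorized.
#' @param alpha_RT Radiosensitivity (Gy^-1).
#' @param constants A [fixed_constants()] object.
#' @param chemo Logical; whether chemotherapy accompanies the fraction.
#' @return Surviving fraction in (0, 1].
#' @examples
#' surviving_fraction(0, 0.05, chemo = TRUE)   # 0.82, chemotherapy only
#' surviving_fraction(2, 0.05, chemo = TRUE)   # 0.82 * exp(-0.12)
#' @export
surviving_fraction <- function(rt_dose, alpha_RT, constants = fixed_constants(),
                               chemo = TRUE) {
  if (any(rt_dose < 0)) stop("rt_dose must be nonnegative")
  stopifnot(alpha_RT > 0)
  beta <- alpha_RT / constants$alpha_beta_ratio
  ifelse(chemo, constants$S_C, 1) * exp(-alpha_RT * rt_dose - beta * rt_dose^2)
}

#' Closed-form logistic growth solution (no treatment)
#'
#' Exact solution of `dN/dt = rho N (1 - N/K)`, used as an independent oracle
#' for the Euler integrator.
#'
#' @param theta A [tumor_parameters()] object.
#' @param t Time(s) in days, >= 0; vectorized.
#' @return Tumor cell count(s) at `t`.
#' @export
closed_form_logistic <- function(theta, t) {
  stopifnot(all(t >= 0))
  with(theta, K * N_initial * exp(rho * t) /
         (K + N_initial * (exp(rho * t) - 1)))
}

#' Simulate a single tumor trajectory
#'
#' Forward-Euler integration of the logistic growth model with instantaneous
#' treatment events. Each event multiplies the cell count by its surviving
#' fraction at the beginning of the event day, before that day's growth
#' steps; the recorded value at a grid time is the pre-event state.
#'
#' @param theta A [tumor_parameters()] object.
#' @param events Event table as returned by [expand_regimen()] (columns
#'   `day`, `rt_dose_gy`, `chemo`); may have zero rows.
#' @param constants A [fixed_constants()] object.
#' @param t_end Final time of the integration (days); defaults to the horizon.
#' @return An object of class `trajectory`: list with `times` (grid, days) and
#'   `cells` (cell counts).
#' @examples
#' th <- tumor_parameters(0.09, 1e11, 1.9e10, 0.05)
#' tr <- simulate_trajectory(th, expand_regimen(soc_regimen()))
#' tr$cells[tr$times == 20]  # pre-RT burden
#' @export
simulate_trajectory <- function(theta, events = NULL,
                                constants = fixed_constants(),
                                t_end = constants$t_finite) {
  m <- param_matrix(theta)
  cells <- simulate_ensemble(m, events = events, constants = constants,
                             t_end = t_end)
  structure(list(times = time_grid(constants, t_end), cells = cells[, 1]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Tumor trajectory: %d grid points over [0, %g] days; N(0) = %.4g, N(end) = %.4g cells\n",
              length(x$times), max(x$times), x$cells[1],
              x$cells[length(x$cells)]))
  invisible(x)
}

#' Simulate an ensemble of trajectories
#'
#' Vectorized forward simulation over a set of parameter draws, e.g. Monte
#' Carlo samples from a posterior. Element-wise identical to repeated
#' [simulate_trajectory()] calls.
#'
#' @param thetas Parameter draws: an n x 4 matrix/data frame with columns
#'   `rho`, `K`, `N_initial`, `alpha_RT`, a list of [tumor_parameters()], or a
#'   single [tumor_parameters()].
#' @param regimen Optional [treatment_regimen()]; expanded to the full
#'   schedule via [treatment_events()]. Ignored if `events` is supplied.
#' @param constants A [fixed_constants()] object.
#' @param events Optional explicit event table (overrides `regimen`).
#' @param t_end Final integration time (days).
#' @return A numeric matrix of cell counts, one column per draw, one row per
#'   grid time (`time_grid(constants, t_end)`).
#' @export
simulate_ensemble <- function(thetas, regimen = NULL,
                              constants = fixed_constants(), events = NULL,
                              t_end = constants$t_finite) {
  m <- param_matrix(thetas)
  if (nrow(m) < 1) stop("empty parameter ensemble")
  if (is.null(events))
    events <- if (is.null(regimen)) empty_events() else
      treatment_events(regimen, constants)
  check_events(events, t_end)
  events <- events[events$day < t_end, , drop = FALSE]
  .euler_ensemble_cpp(m[, "rho"], m[, "K"], m[, "N_initial"], m[, "alpha_RT"],
                      as.integer(events$day), as.numeric(events$rt_dose_gy),
                      as.logical(events$chemo), constants$S_C,
                      constants$alpha_beta_ratio, constants$dt, t_end)
}

empty_events <- function() {
  data.frame(day = integer(), rt_dose_gy = numeric(), chemo = logical())
}

check_events <- function(events, t_end) {
  stopifnot(all(c("day", "rt_dose_gy", "chemo") %in% names(events)))
  if (nrow(events) && any(events$day < 0))
    stop("event days must be nonnegative")
  if (nrow(events) && any(events$rt_dose_gy < 0))
    stop("event RT doses must be nonnegative")
  invisible(events)
}

#' Export a trajectory as a CSV table
#'
#' @param trajectory A `trajectory` object.
#' @param file Path of the CSV file to write (columns `time_days`, `cells`).
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  utils::write.csv(
    data.frame(time_days = trajectory$times, cells = trajectory$cells),
    file, row.names = FALSE)
  invisible(file)
}
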