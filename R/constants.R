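#' Fixed model and treatment-schedule constants
#'
#' Collects the non-patient-specific constants of the tumor-growth and
#' treatment model: the chemotherapy surviving fraction, the linear-quadratic
#' alpha/beta ratio, the integration step, the simulation horizon, and the
#' radiotherapy calendar (first RT day, number of weeks, fractions per week).
#'
#' @param S_C Surviving fraction from a single chemotherapy dose
#'   (dimensionless, in (0, 1]).
#' @param alpha_beta_ratio Ratio alpha_RT / beta_RT of the linear-quadratic
#'   cell-survival model (Gy).
#' @param dt Forward-Euler integration step (days). Must divide 1 day so that
#'   treatment-event days fall exactly on grid points.
#' @param t_finite Simulation horizon after surgery (days).
#' @param rt_start_day First day of radiotherapy (days after surgery).
#' @param weeks Number of radiotherapy weeks (length of the weekly dose
#'   vector).
#' @param fractions_per_week Number of consecutive RT treatment days per RT
#'   week.
#' @param chemo_days_per_week Number of days per RT week on which
#'   chemotherapy is administered, counted from the start of the week
#'   (default 7: concomitant chemotherapy is given daily, weekends
#'   included, throughout the six weeks).
#'
#' @return An object of class `fixed_constants` (a named list) with the above
#'   fields plus `t_post_rt`, the day RT concludes (`rt_start_day + 7 * weeks`).
#' @examples
#' cst <- fixed_constants()
#' cst$t_post_rt  # 62
#' @export
fixed_constants <- function(S_C = 0.82, alpha_beta_ratio = 10, dt = 0.2,
                            t_finite = 152, rt_start_day = 20, weeks = 6,
                            fractions_per_week = 5,
                            chemo_days_per_week = 7) {
  stopifnot(
    "S_C must be in (0, 1]" = is.numeric(S_C) && S_C > 0 && S_C <= 1,
    "alpha_beta_ratio must be positive" = alpha_beta_ratio > 0,
    "dt must be positive" = dt > 0,
    "t_finite must be positive" = t_finite > 0,
    "rt_start_day must be nonnegative" = rt_start_day >= 0,
    "weeks must be a positive integer" = weeks >= 1,
    "fractions_per_week must be in 1..7" =
      fractions_per_week >= 1 && fractions_per_week <= 7,
    "chemo_days_per_week must be in fractions_per_week..7" =
      chemo_days_per_week >= fractions_per_week && chemo_days_per_week <= 7
  )
  steps_per_day <- 1 / dt
  if (abs(steps_per_day - round(steps_per_day)) > 1e-8)
    stop("dt must divide 1 day so event days align with the time grid")
  t_post_rt <- rt_start_day + 7 * weeks
  if (t_post_rt > t_finite)
    stop("RT schedule (ends day ", t_post_rt,
         ") must fit within the simulation horizon t_finite = ", t_finite)
  structure(
    list(S_C = S_C, alpha_beta_ratio = alpha_beta_ratio, dt = dt,
         t_finite = t_finite, rt_start_day = rt_start_day, weeks = weeks,
         fractions_per_week = fractions_per_week,
         chemo_days_per_week = chemo_days_per_week, t_post_rt = t_post_rt),
    class = "fixed_constants"
  )
}

#' @export
print.fixed_constants <- function(x, ...) {
  cat("Fixed model constants\n")
  cat(sprintf("  S_C = %g, alpha/beta = %g Gy, dt = %g days\n",
              x$S_C, x$alpha_beta_ratio, x$dt))
  cat(sprintf("  horizon %g days; RT days %g-%g (%d weeks x %d fractions)\n",
              x$t_finite, x$rt_start_day, x$t_post_rt - 3, x$weeks,
              x$fractions_per_week))
  invisible(x)
}

time_grid <- function(constants, t_end = constants$t_finite) {
  seq(0, t_end, by = constants$dt)
}

grid_index <- function(t, constants) {
  j <- t / constants$dt
  if (any(abs(j - round(j)) > 1e-8))
    stop("time(s) ", paste(t[abs(j - round(j)) > 1e-8], collapse = ", "),
         " do not lie on the integration grid (dt = ", constants$dt, ")")
  as.integer(round(j)) + 1L
}
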