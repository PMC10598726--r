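#' Optimization-under-uncertainty settings
#'
#' @param lambda Dose-penalty weight on the l1 norm of the weekly dose vector
#'   (days of risk per Gy/day summed over weeks). Default 0.001: small enough
#'   never to trade tumor control for dose, large enough to drive the dose
#'   down along TTP plateaus.
#' @param restarts Number of multi-start restarts of the local optimizer.
#' @param max_evals_per_restart Objective-evaluation budget per restart.
#' @param n_MC Monte-Carlo sample size for each risk evaluation (a fixed draw
#'   subset, common random numbers, so the objective is deterministic).
#' @param seed Integer seed (draw-subset selection and restart points).
#' @return An object of class `ouu_settings`.
#' @export
ouu_settings <- function(lambda = 0.001, restarts = 20,
                         max_evals_per_restart = 200, n_MC = 5000, seed = 1L) {
  stopifnot(lambda >= 0, restarts >= 1, max_evals_per_restart >= 10,
            n_MC >= 1)
  structure(list(lambda = lambda, restarts = as.integer(restarts),
                 max_evals_per_restart = as.integer(max_evals_per_restart),
                 n_MC = as.integer(n_MC), seed = as.integer(seed)),
            class = "ouu_settings")
}

#' Penalized superquantile risk objective
#'
#' The scalarized objective of the dose optimization:
#' `superquantile(-TTP, alpha) + lambda * ||u||_1`, evaluated on a fixed
#' Monte-Carlo draw set (common random numbers), with week 1 fixed at the
#' standard-of-care 2 Gy/day.
#'
#' @param free_doses Doses for weeks 2..n_u (Gy/day), each in \[0, 10\].
#' @param draws Fixed n_MC x 4 parameter draw matrix.
#' @param spec A [risk_spec()].
#' @param lambda Dose penalty weight.
#' @param constants A [fixed_constants()] object.
#' @return Scalar objective value (days scale, negative when control is
#'   good).
#' @export
penalized_risk_objective <- function(free_doses, draws, spec = risk_spec(),
                                     lambda = 0.001,
                                     constants = fixed_constants()) {
  if (length(free_doses) != constants$weeks - 1)
    stop("free_doses must cover weeks 2..", constants$weeks)
  if (any(free_doses < 0 | free_doses > 10))
    stop("doses must lie in [0, 10] Gy/day")
  u <- c(2, free_doses)
  reg <- treatment_regimen(u, constants)
  superquantile(qoi_samples(draws, reg, constants), spec$alpha) +
    lambda * sum(u)
}

#' Optimize a patient's weekly RT dose schedule under uncertainty
#'
#' Minimizes the penalized superquantile risk of negative TTP over the doses
#' of weeks 2..n_u (week 1 fixed at 2 Gy/day), subject to the box \[0, 10\]
#' Gy/day and the total-dose constraint `5 * ||u||_1 <= D_max`. Multi-start
#' local search: restart 1 starts at the standard of care (projected into the
#' feasible set if needed), the rest at random feasible points; each restart
#' runs a log-barrier Nelder-Mead search. Every feasible evaluated candidate
#' is tracked and the best (ties broken toward lower total dose) is returned,
#' so the result is never worse than any candidate considered, including the
#' standard of care when feasible.
#'
#' @param posterior `posterior_samples` object or n x 4 draw matrix.
#' @param D_max Total-dose threshold (Gy), >= 10 (week 1 alone delivers
#'   10 Gy).
#' @param spec A [risk_spec()].
#' @param settings An [ouu_settings()].
#' @param constants A [fixed_constants()] object.
#' @return An object of class `optimal_regimen`: list with `regimen`
#'   (the optimal [treatment_regimen()]), `risk_value` (superquantile of the
#'   QoI, days, negative scale), `ttp_superquantile` (days), `total_dose`
#'   (Gy), `objective` (penalized), `D_max`, `evals`.
#' @export
optimize_regimen <- function(posterior, D_max, spec = risk_spec(),
                             settings = ouu_settings(),
                             constants = fixed_constants()) {
  stopifnot("D_max must be at least 10 Gy (week-1 SOC dose)" = D_max >= 10)
  d <- constants$weeks - 1
  fpw <- constants$fractions_per_week
  draws <- posterior_subset(posterior, settings$n_MC, settings$seed)
  lambda <- settings$lambda

  # budget for the free doses: fpw*(2 + sum(free)) <= D_max
  budget <- D_max / fpw - 2
  evals <- 0L
  best <- list(obj = Inf, dose = Inf, free = NULL, risk = NA_real_)

  consider <- function(free, obj, risk) {
    td <- fpw * (2 + sum(free))
    if (obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && td < best$dose))
      best <<- list(obj = obj, dose = td, free = free, risk = risk)
  }
  evaluate <- function(free) {
    risk <- superquantile(
      qoi_samples(draws, treatment_regimen(c(2, free), constants), constants),
      spec$alpha)
    obj <- risk + lambda * (2 + sum(free))
    evals <<- evals + 1L
    consider(free, obj, risk)
    list(obj = obj, risk = risk)
  }

  if (budget <= 1e-9) {
    # only the week-1 dose is admissible: unique feasible vertex
    evaluate(rep(0, d))
  } else {
    # explicit boundary candidates (constrOptim needs a strict interior)
    evaluate(rep(0, d))
    if (fpw * (2 + 2 * d) <= D_max + 1e-9) evaluate(rep(2, d)) # SOC
    ui <- rbind(diag(d), -diag(d), matrix(-1, 1, d))
    ci <- c(rep(0, d), rep(-10, d), -budget)
    set.seed(patient_seed(settings$seed, 0L, stage = 202L))
    starts <- lapply(seq_len(settings$restarts), function(r) {
      if (r == 1) {
        s <- rep(min(2, budget / d), d)       # SOC, projected if infeasible
      } else {
        s <- stats::runif(d, 0, min(10, budget))
        if (sum(s) > budget) s <- s * budget / sum(s)
      }
      pmin(pmax(s, 1e-6), 10 - 1e-6) * 0.999
    })
    for (s in starts) {
      budget_left <- settings$max_evals_per_restart
      f <- function(free) {
        if (budget_left <= 0L) stop(eval_budget_condition())
        budget_left <<- budget_left - 1L
        evaluate(free)$obj
      }
      tryCatch(
        stats::constrOptim(s, f, grad = NULL, ui = ui, ci = ci,
                           control = list(maxit = settings$max_evals_per_restart),
                           outer.iterations = 5),
        gliotwin_eval_budget = function(e) NULL,
        error = function(e) {
          if (!inherits(e, "gliotwin_eval_budget"))
            warning("optimizer restart failed: ", conditionMessage(e))
          NULL
        })
    }
    # snap near-boundary doses of the incumbent to exact bounds
    snapped <- best$free
    snapped[snapped < 1e-4] <- 0
    snapped[snapped > 10 - 1e-4] <- 10
    if (sum(snapped) <= budget + 1e-9 && !identical(snapped, best$free))
      evaluate(snapped)
  }

  u_star <- treatment_regimen(c(2, best$free), constants)
  structure(list(regimen = u_star, risk_value = best$risk,
                 ttp_superquantile = -best$risk,
                 total_dose = fpw * sum(u_star$weekly_doses),
                 objective = best$obj, D_max = D_max, evals = evals,
                 alpha = spec$alpha, lambda = lambda),
            class = "optimal_regimen")
}

eval_budget_condition <- function() {
  structure(class = c("gliotwin_eval_budget", "error", "condition"),
            list(message = "evaluation budget reached", call = NULL))
}

#' @export
print.optimal_regimen <- function(x, ...) {
  cat(sprintf("Optimal regimen at D_max = %g Gy (alpha = %g):\n", x$D_max,
              x$alpha))
  cat("  u* =", paste(format(x$regimen$weekly_doses, digits = 3),
                      collapse = ", "), "Gy/day\n")
  cat(sprintf("  total dose %.2f Gy; TTP superquantile %.1f days (%d evals)\n",
              x$total_dose, x$ttp_superquantile, x$evals))
  invisible(x)
}

#' Pareto sweep over total-dose thresholds
#'
#' Solves the constrained dose optimization for each `D_max` on the grid,
#' tracing the Pareto front between tumor control (TTP superquantile) and
#' toxicity (total dose).
#'
#' @param posterior `posterior_samples` object or n x 4 draw matrix.
#' @param grid Vector of `D_max` values (Gy); default
#'   `c(40, 50, 60, 70, 80, 100)`.
#' @param spec A [risk_spec()].
#' @param settings An [ouu_settings()].
#' @param constants A [fixed_constants()] object.
#' @return An object of class `pareto_set`: list of `optimal_regimen`
#'   objects, with a `summary` data frame attribute.
#' @export
pareto_sweep <- function(posterior, grid = c(40, 50, 60, 70, 80, 100),
                         spec = risk_spec(), settings = ouu_settings(),
                         constants = fixed_constants()) {
  stopifnot(length(grid) >= 1)
  sols <- lapply(grid, function(D)
    optimize_regimen(posterior, D, spec, settings, constants))
  structure(sols, class = "pareto_set", D_max_grid = grid)
}

#' Summarize a Pareto set as a data frame
#'
#' @param object A `pareto_set`.
#' @param ... Unused.
#' @return Data frame with one row per `D_max`: `D_max`, `total_dose`,
#'   `ttp_superquantile`, `risk_value` and the weekly doses.
#' @export
summary.pareto_set <- function(object, ...) {
  df <- do.call(rbind, lapply(object, function(s)
    data.frame(D_max = s$D_max, total_dose = s$total_dose,
               ttp_superquantile = s$ttp_superquantile,
               risk_value = s$risk_value,
               t(stats::setNames(s$regimen$weekly_doses,
                                 paste0("u", seq_along(s$regimen$weekly_doses)))))))
  rownames(df) <- NULL
  df
}

#' @export
print.pareto_set <- function(x, ...) {
  cat("Pareto set over D_max grid:\n")
  print(summary(x), digits = 4)
  invisible(x)
}
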