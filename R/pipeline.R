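#' Experiment configuration
#'
#' Bundles all settings of the in-silico study: cohort generation,
#' observation schedule, MCMC, risk level, dose optimization and survival
#' analysis. Defaults reproduce the reference study conditions (100 patients,
#' observations on days 0/20/27 with sigma = 2e9 cells, alpha = 0.95,
#' lambda = 0.001, D_max grid 40..100 Gy, n_MC = 5000, 20 x 200 evaluations);
#' every field can be overridden for scaled-down runs.
#'
#' @param n_p Number of patients.
#' @param seed Master seed; all stage substreams derive from it.
#' @param prior `prior_spec` for cohort generation and calibration.
#' @param obs_times Observation days.
#' @param sigma Observation noise sd (cells).
#' @param mcmc [mcmc_settings()] (its seed field is replaced per patient).
#' @param risk [risk_spec()].
#' @param ouu [ouu_settings()] (its seed field is replaced per patient).
#' @param d_max_grid Total-dose thresholds for the Pareto sweep (Gy).
#' @param survival_tolerance Matching tolerance for the dose-reduction
#'   analysis (days).
#' @param constants [fixed_constants()].
#' @param theta_true Optional list of [tumor_parameters()] to use as ground
#'   truth instead of sampling the prior (length `n_p`), e.g. case-study
#'   patients.
#' @param outdir Optional output directory; when set, per-patient artifacts
#'   are persisted and reused on rerun (resumable stages).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_p = 100, seed = 1L, prior = default_prior(),
                              obs_times = c(0, 20, 27), sigma = 2e9,
                              mcmc = mcmc_settings(), risk = risk_spec(),
                              ouu = ouu_settings(),
                              d_max_grid = c(40, 50, 60, 70, 80, 100),
                              survival_tolerance = 1,
                              constants = fixed_constants(),
                              theta_true = NULL, outdir = NULL) {
  stopifnot(n_p >= 1, inherits(prior, "prior_spec"),
            inherits(mcmc, "mcmc_settings"), inherits(risk, "risk_spec"),
            inherits(ouu, "ouu_settings"),
            inherits(constants, "fixed_constants"),
            length(d_max_grid) >= 1, sigma > 0)
  if (!is.null(theta_true)) stopifnot(length(theta_true) == n_p)
  structure(list(n_p = as.integer(n_p), seed = as.integer(seed),
                 prior = prior, obs_times = obs_times, sigma = sigma,
                 mcmc = mcmc, risk = risk, ouu = ouu,
                 d_max_grid = d_max_grid,
                 survival_tolerance = survival_tolerance,
                 constants = constants, theta_true = theta_true,
                 outdir = outdir),
            class = "experiment_config")
}

# Short configuration fingerprint used to validate cached artifacts.
config_fingerprint <- function(config) {
  paste(config$seed, config$sigma,
        paste(config$obs_times, collapse = "/"),
        config$mcmc$chains, config$mcmc$draws_per_chain, config$mcmc$warmup,
        config$risk$alpha, config$ouu$lambda, config$ouu$restarts,
        config$ouu$max_evals_per_restart, config$ouu$n_MC,
        paste(config$d_max_grid, collapse = "/"),
        config$constants$dt, config$constants$t_finite, sep = "|")
}

#' Run the digital-twin pipeline for one patient
#'
#' Generates (or loads) the patient's ground truth and observations,
#' calibrates the digital twin, computes the SOC TTP superquantile, and runs
#' the Pareto dose-optimization sweep. The ground truth is persisted in a
#' hidden block of the patient record and is never read by calibration or
#' optimization.
#'
#' @param config An [experiment_config()].
#' @param patient_id Patient index in `1..n_p`.
#' @param through Last stage to execute: `"cohort"` (truth + observations),
#'   `"calibrate"` (+ posterior), or `"optimize"` (+ SOC risk, Pareto sweep,
#'   grouping and dose reduction; the default). Later stages reuse persisted
#'   artifacts of earlier ones when `config$outdir` is set.
#' @return List with `patient_id`, `observations`, `posterior`,
#'   `soc_ttp_superquantile`, `pareto` (a `pareto_set`), `group` and
#'   `dose_reduction` (later fields `NULL` when not run).
#' @export
run_patient <- function(config, patient_id,
                        through = c("optimize", "calibrate", "cohort")) {
  through <- match.arg(through)
  cst <- config$constants
  fp <- config_fingerprint(config)
  cache <- patient_cache_path(config, patient_id)
  if (through == "optimize" && !is.null(cache) &&
      file.exists(cache$report)) {
    rep <- jsonlite::read_json(cache$report, simplifyVector = TRUE)
    if (identical(rep$fingerprint, fp)) return(load_patient_report(rep, cst))
  }

  theta_true <- if (!is.null(config$theta_true))
    config$theta_true[[patient_id]]
  else
    sample_cohort(config$prior, 1, patient_seed(config$seed, patient_id))[[1]]

  obs <- generate_observations(
    theta_true, soc_regimen(cst), config$obs_times, config$sigma,
    seed = patient_seed(config$seed, patient_id, stage = 1L), constants = cst)
  if (!is.null(cache))
    patient_record_json(patient_id, theta_true, obs,
                        patient_seed(config$seed, patient_id),
                        file = cache$record)
  if (through == "cohort")
    return(list(patient_id = patient_id,
                theta_true_hidden = unclass(theta_true),
                observations = obs, posterior = NULL))

  posterior <- load_cached_posterior(cache, fp)
  if (is.null(posterior)) {
    mc <- config$mcmc
    mc$seed <- patient_seed(config$seed, patient_id, stage = 2L)
    posterior <- calibrate(obs, config$prior, soc_regimen(cst), mc, cst)
    if (!is.null(cache)) persist_posterior(posterior, cache, fp)
  }
  if (through == "calibrate")
    return(list(patient_id = patient_id,
                theta_true_hidden = unclass(theta_true),
                observations = obs, posterior = posterior))

  ou <- config$ouu
  ou$seed <- patient_seed(config$seed, patient_id, stage = 3L)
  soc_draws <- posterior_subset(posterior, ou$n_MC, ou$seed)
  soc_sq <- -superquantile(qoi_samples(soc_draws, soc_regimen(cst), cst),
                           config$risk$alpha)
  pareto <- pareto_sweep(posterior, config$d_max_grid, config$risk, ou, cst)

  res <- list(
    patient_id = patient_id,
    theta_true_hidden = unclass(theta_true),
    observations = obs,
    posterior = posterior,
    soc_ttp_superquantile = soc_sq,
    pareto = pareto,
    group = as.character(classify_progressor(
      soc_sq, cap = cst$t_finite - cst$rt_start_day)),
    dose_reduction = dose_reduction_analysis(pareto, soc_sq,
                                             config$survival_tolerance)
  )
  if (!is.null(cache)) persist_patient(res, cache, fp, config)
  res
}

patient_cache_path <- function(config, patient_id) {
  if (is.null(config$outdir)) return(NULL)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$outdir, sprintf("patient_%03d", patient_id))
  list(report = paste0(base, "_report.json"),
       record = paste0(base, "_record.json"),
       posterior = paste0(base, "_posterior.csv"))
}

persist_posterior <- function(posterior, cache, fp) {
  utils::write.csv(as.data.frame(posterior$draws), cache$posterior,
                   row.names = FALSE)
  jsonlite::write_json(
    list(fingerprint = fp, diagnostics = posterior$diagnostics,
         accept_rate = posterior$accept_rate,
         n_initial_prior = unclass(posterior$n_initial_prior)),
    paste0(cache$posterior, ".diagnostics.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
}

load_cached_posterior <- function(cache, fp) {
  if (is.null(cache)) return(NULL)
  side <- paste0(cache$posterior, ".diagnostics.json")
  if (!file.exists(cache$posterior) || !file.exists(side)) return(NULL)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$fingerprint, fp)) return(NULL)
  draws <- as.matrix(utils::read.csv(cache$posterior))
  structure(list(draws = draws, diagnostics = meta$diagnostics,
                 accept_rate = meta$accept_rate,
                 n_initial_prior = do.call(truncnorm_spec,
                                           as.list(meta$n_initial_prior)),
                 settings = NULL, cached = TRUE),
            class = "posterior_samples")
}

persist_patient <- function(res, cache, fp, config) {
  jsonlite::write_json(
    list(fingerprint = fp, patient_id = res$patient_id,
         soc_ttp_superquantile = res$soc_ttp_superquantile,
         group = res$group, dose_reduction = res$dose_reduction,
         pareto = summary(res$pareto),
         observations = list(times = res$observations$times,
                             values = res$observations$values,
                             sigma = res$observations$sigma)),
    cache$report, auto_unbox = TRUE, digits = NA, dataframe = "rows")
}

# Rebuild the light-weight per-patient result from a cached report (the
# posterior draws are not reloaded; cohort summaries do not need them).
load_patient_report <- function(rep, constants) {
  pareto <- lapply(seq_len(nrow(rep$pareto)), function(i) {
    row <- rep$pareto[i, ]
    u <- as.numeric(row[grep("^u[0-9]+$", names(row))])
    structure(list(regimen = treatment_regimen(u, constants),
                   risk_value = row$risk_value,
                   ttp_superquantile = row$ttp_superquantile,
                   total_dose = row$total_dose, objective = NA_real_,
                   D_max = row$D_max, evals = NA_integer_),
              class = "optimal_regimen")
  })
  class(pareto) <- "pareto_set"
  list(patient_id = rep$patient_id, observations = NULL, posterior = NULL,
       soc_ttp_superquantile = rep$soc_ttp_superquantile, pareto = pareto,
       group = rep$group, dose_reduction = rep$dose_reduction,
       cached = TRUE)
}

#' Run the full in-silico experiment
#'
#' Executes the cohort / calibration / optimization / survival stages for
#' every patient with derived random substreams, and assembles the
#' cohort-level report: per-patient table, Kaplan-Meier curves for SOC and
#' each `D_max`, and logrank p-values against SOC.
#'
#' @param config An [experiment_config()].
#' @param patients Optional subset of patient indices to run (default all).
#' @param progress Logical; print one line per patient.
#' @return An object of class `cohort_report`: list with `patients` (data
#'   frame), `km` (list of `survival_curve`s named "SOC" and "OUU:<D> Gy"),
#'   `logrank` (data frame of p-values vs SOC), `config`, and the raw
#'   per-patient results in `results`.
#' @export
run_experiment <- function(config, patients = seq_len(config$n_p),
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  results <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    i <- patients[k]
    t0 <- proc.time()[["elapsed"]]
    results[[k]] <- tryCatch(run_patient(config, i), error = function(e) {
      warning("patient ", i, " failed: ", conditionMessage(e))
      list(patient_id = i, failed = TRUE, error = conditionMessage(e))
    })
    if (progress)
      message(sprintf("patient %d: %s (%.1f s)", i,
                      if (isTRUE(results[[k]]$failed)) "FAILED" else
                        results[[k]]$group,
                      proc.time()[["elapsed"]] - t0))
  }
  build_cohort_report(results, config)
}

build_cohort_report <- function(results, config) {
  ok <- !vapply(results, function(r) isTRUE(r$failed), logical(1))
  done <- results[ok]
  if (length(done) == 0) stop("no patient completed successfully")
  grid <- config$d_max_grid
  cap <- config$constants$t_finite - config$constants$rt_start_day

  rows <- lapply(done, function(r) {
    sq <- vapply(r$pareto, `[[`, numeric(1), "ttp_superquantile")
    dose <- vapply(r$pareto, `[[`, numeric(1), "total_dose")
    df <- data.frame(patient_id = r$patient_id, group = r$group,
                     soc_ttp_superquantile = r$soc_ttp_superquantile,
                     dose_reduction = r$dose_reduction)
    for (j in seq_along(grid)) {
      df[[sprintf("ttp_sq_%g", grid[j])]] <- sq[j]
      df[[sprintf("dose_%g", grid[j])]] <- dose[j]
    }
    df
  })
  patients <- do.call(rbind, rows)

  km <- list(SOC = km_curve(patients$soc_ttp_superquantile, cap))
  logrank <- data.frame(D_max = grid, statistic = NA_real_,
                        p_value = NA_real_)
  for (j in seq_along(grid)) {
    ttp_j <- patients[[sprintf("ttp_sq_%g", grid[j])]]
    km[[sprintf("OUU:%g Gy", grid[j])]] <- km_curve(ttp_j, cap)
    lr <- logrank_test(ttp_j, patients$soc_ttp_superquantile, cap)
    logrank$statistic[j] <- lr$statistic
    logrank$p_value[j] <- lr$p_value
  }

  rep <- structure(list(patients = patients, km = km, logrank = logrank,
                        n_failed = sum(!ok), config = config,
                        results = results),
                   class = "cohort_report")
  if (!is.null(config$outdir)) {
    utils::write.csv(patients,
                     file.path(config$outdir, "cohort_patients.csv"),
                     row.names = FALSE)
    utils::write.csv(logrank, file.path(config$outdir, "cohort_logrank.csv"),
                     row.names = FALSE)
    utils::write.csv(compare_to_soc(rep),
                     file.path(config$outdir, "cohort_summary.csv"),
                     row.names = FALSE)
    for (nm in names(km))
      write_survival_csv(km[[nm]],
                         file.path(config$outdir,
                                   paste0("km_", gsub("[: ]", "_", nm),
                                          ".csv")))
  }
  rep
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d patients (%d failed)\n",
              nrow(x$patients), x$n_failed))
  print(table(x$patients$group))
  cat("\nLogrank vs SOC:\n")
  print(x$logrank, digits = 3)
  invisible(x)
}

#' Summarize optimized regimens against the standard of care
#'
#' Per-group and cohort medians of the per-patient change in TTP
#' alpha-superquantile, `TTP_sq(OUU:D Gy) - TTP_sq(SOC)`, at each `D_max`,
#' plus median achievable dose reductions at matched tumor control.
#'
#' @param report A `cohort_report` from [run_experiment()].
#' @return Data frame with one row per (group, D_max), columns
#'   `group`, `D_max`, `n`, `median_ttp_change`, `median_dose_reduction`.
#' @export
compare_to_soc <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  p <- report$patients
  grid <- report$config$d_max_grid
  groups <- c("cohort", levels(factor(p$group)))
  out <- list()
  for (g in groups) {
    sel <- if (g == "cohort") rep(TRUE, nrow(p)) else p$group == g
    for (D in grid) {
      diff <- p[[sprintf("ttp_sq_%g", D)]][sel] -
        p$soc_ttp_superquantile[sel]
      out[[length(out) + 1]] <- data.frame(
        group = g, D_max = D, n = sum(sel),
        median_ttp_change = stats::median(diff),
        median_dose_reduction = stats::median(p$dose_reduction[sel]))
    }
  }
  do.call(rbind, out)
}
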