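test_that("progressor classification partitions the cohort at 72 days and the cap", {
  expect_equal(as.character(classify_progressor(132)), "late")
  expect_equal(as.character(classify_progressor(42.2)), "early")
  expect_equal(as.character(classify_progressor(100)), "intermediate")
  expect_equal(as.character(classify_progressor(72)), "early")      # boundary
  expect_equal(as.character(classify_progressor(131.9)), "intermediate")
  x <- c(30, 72, 72.2, 100, 131.8, 132)
  g <- classify_progressor(x)
  expect_equal(sum(table(g)), length(x))  # a partition
  expect_error(classify_progressor(133))
})

test_that("Kaplan-Meier matches the hand-computed product-limit example", {
  k <- km_curve(c(30, 60, 132), censor_time = 132)
  expect_equal(k$time, c(30, 60))
  expect_equal(k$survival, c(2 / 3, 1 / 3))
  expect_equal(k$at_risk, c(3L, 2L))
  expect_equal(k$events, c(1L, 1L))
  # no drop at the censor time
  expect_equal(survival_at(k, 132), 1 / 3)
})

test_that("without censoring the KM curve is one minus the empirical CDF", {
  set.seed(8)
  x <- sort(sample(seq(10, 120, by = 0.2), 25))
  k <- km_curve(x, censor_time = 132)
  expect_equal(k$survival, 1 - ecdf(x)(k$time), tolerance = 1e-12)
  # fully censored cohort stays at one
  k_all <- km_curve(rep(132, 10), censor_time = 132)
  expect_equal(nrow(k_all), 0)
  expect_equal(survival_at(k_all, c(50, 131)), c(1, 1))
  expect_error(km_curve(numeric(0)), "empty")
})

test_that("KM estimator agrees with the survival package", {
  set.seed(9)
  x <- c(round(runif(40, 20, 131), 1), rep(132, 10))
  k <- km_curve(x, censor_time = 132)
  sf <- survival::survfit(survival::Surv(x, x < 132) ~ 1)
  ours <- survival_at(k, sf$time)
  expect_equal(ours, sf$surv, tolerance = 1e-12)
})

test_that("logrank test is null on identical cohorts and matches survdiff", {
  x <- c(30, 45, 60, 80, 132, 132)
  same <- logrank_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(10)
  a <- round(runif(30, 20, 132), 1)
  b <- round(runif(25, 40, 132), 1)
  ours <- logrank_test(a, b, censor_time = 132)
  tt <- c(a, b)
  ev <- as.integer(tt < 132)
  gg <- c(rep(1, 30), rep(2, 25))
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
  expect_equal(ours$statistic, ref$chisq, tolerance = 1e-10)
  expect_equal(ours$p_value,
               pchisq(ref$chisq, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("logrank detects a strongly dominated cohort and degrades gracefully", {
  set.seed(11)
  a <- runif(40, 20, 60)
  b <- runif(40, 80, 130)
  expect_lt(logrank_test(a, b)$p_value, 0.05)
  expect_warning(res <- logrank_test(rep(132, 5), rep(132, 7)), "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("logrank p-values are approximately uniform under the null", {
  set.seed(12)
  p <- replicate(1000, {
    a <- runif(20, 20, 131.9)
    b <- runif(20, 20, 131.9)
    logrank_test(a, b, censor_time = 132)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("dose reduction picks the cheapest regimen matching SOC control", {
  mk <- function(D, dose, ttp) structure(
    list(D_max = D, total_dose = dose, ttp_superquantile = ttp),
    class = "optimal_regimen")
  # 50 Gy ties SOC within 1 day, 40 Gy does not -> reduction 10 Gy
  pareto <- list(mk(40, 40, 80), mk(50, 50, 88.6), mk(60, 60, 89))
  expect_equal(dose_reduction_analysis(pareto, 89, tolerance = 1), 10)
  # all solutions at the cap -> reduction to the cheapest solution
  flat <- list(mk(40, 22, 132), mk(50, 30, 132), mk(60, 35, 132))
  expect_equal(dose_reduction_analysis(flat, 132), 60 - 22)
  # only the 60 Gy solution matches -> no reduction
  none <- list(mk(40, 40, 70), mk(50, 50, 75), mk(60, 60, 89))
  expect_equal(dose_reduction_analysis(none, 89), 0)
})

test_that("bootstrap survival variance vanishes in degenerate cases and shrinks with sample size", {
  sets <- list(runif(200, 30, 130), runif(200, 40, 132), runif(200, 20, 100))
  one <- survival_variance_bootstrap(sets, n_boot = 1, seed = 1)
  expect_true(all(one$variance == 0))
  degenerate <- list(rep(60, 100), rep(90, 100), rep(132, 100))
  v0 <- survival_variance_bootstrap(degenerate, n_boot = 30, seed = 2)
  expect_true(all(v0$variance == 0))
  # Monte-Carlo convergence: larger per-patient samples -> smaller variance
  mkset <- function(n, seed) {
    set.seed(seed)
    lapply(1:8, function(i) runif(n, 20, 132))
  }
  v <- vapply(c(100, 1000, 10000), function(n)
    mean(survival_variance_bootstrap(mkset(n, 3), n_boot = 40,
                                     seed = 4)$variance), numeric(1))
  expect_true(all(diff(v) < 0))
})
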