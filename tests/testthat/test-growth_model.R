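test_that("regimen expansion places fractions on the first five days of each RT week", {
  ev <- expand_regimen(soc_regimen())
  expect_equal(nrow(ev), 30)
  expect_true(all(ev$rt_dose_gy == 2))
  expect_true(all(ev$chemo))
  expect_equal(sum(ev$rt_dose_gy), 60)  # 30 fractions of 2 Gy
  expected_days <- as.integer(outer(0:4, 20 + 7 * (0:5), `+`))
  expect_setequal(ev$day, expected_days)
})

test_that("zero-dose weeks still carry chemotherapy events", {
  reg <- treatment_regimen(c(2, 0, 0, 0, 0, 0))
  ev <- expand_regimen(reg)
  expect_equal(nrow(ev), 30)
  expect_equal(sum(ev$rt_dose_gy == 2), 5)
  expect_equal(sum(ev$rt_dose_gy == 0), 25)
  expect_true(all(ev$chemo))
  expect_equal(sum(ev$rt_dose_gy), 5 * sum(reg$weekly_doses))
})

test_that("regimen validation rejects bad lengths and out-of-box doses", {
  expect_error(treatment_regimen(rep(2, 5)), "one dose per RT week")
  expect_error(treatment_regimen(c(2, 2, 2, 2, 2, 11)), "\\[0, 10\\]")
  expect_error(treatment_regimen(c(-1, 2, 2, 2, 2, 2)), "\\[0, 10\\]")
})

test_that("surviving fraction follows the linear-quadratic model with chemo factor", {
  expect_equal(surviving_fraction(0, 0.05, chemo = TRUE), 0.82)
  expect_equal(surviving_fraction(0, 0.05, chemo = FALSE), 1.0)
  # d = 2 Gy, alpha = 0.05 -> beta = 0.005, S = 0.82 * exp(-0.12)
  expect_equal(surviving_fraction(2, 0.05, chemo = TRUE), 0.82 * exp(-0.12),
               tolerance = 1e-12)
  expect_error(surviving_fraction(-1, 0.05), "nonnegative")
})

test_that("surviving fraction is strictly decreasing in dose", {
  d <- seq(0, 10, by = 0.5)
  s <- surviving_fraction(d, 0.05, chemo = TRUE)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 0.82))
})

test_that("Euler integration matches the closed-form logistic within 0.5%", {
  th <- tumor_parameters(0.09, 1e11, 1.9e10, 0.05)
  tr <- simulate_trajectory(th)  # no events
  exact <- closed_form_logistic(th, tr$times)
  expect_lt(max(abs(tr$cells - exact) / exact), 0.005)
  # the worked value at t = 20 days
  expect_equal(closed_form_logistic(th, 20), 5.866e10, tolerance = 1e-3)
  expect_equal(tr$cells[tr$times == 20], 5.87e10, tolerance = 5e-3)
})

test_that("halving the step size roughly halves the Euler error", {
  th <- tumor_parameters(0.09, 1e11, 1.9e10, 0.05)
  err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    cst <- fixed_constants(dt = dt)
    tr <- simulate_trajectory(th, constants = cst)
    max(abs(tr$cells - closed_form_logistic(th, tr$times)) /
          closed_form_logistic(th, tr$times))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[2], 1.6)  # ~linear convergence
  expect_lt(err[1] / err[2], 2.4)
})

test_that("degenerate growth cases are exact", {
  cst <- fixed_constants()
  # zero net growth (rho -> 0 limit approximated by tiny rho)
  th0 <- tumor_parameters(1e-14, 1e11, 1.9e10, 0.05)
  tr0 <- simulate_trajectory(th0, constants = cst)
  expect_equal(tr0$cells, rep(1.9e10, length(tr0$times)), tolerance = 1e-9)
  # at carrying capacity the state is a fixed point (N just below K)
  thK <- tumor_parameters(0.09, 1e11, 1e11 * (1 - 1e-12), 0.05)
  trK <- simulate_trajectory(thK, constants = cst)
  expect_equal(trK$cells / 1e11, rep(1, length(trK$times)), tolerance = 1e-9)
  expect_equal(tr0$cells[1], th0$N_initial)
})

test_that("compiled integrator agrees with a plain-R reference including events", {
  cst <- fixed_constants()
  th <- case_study_patients()$p2
  ev <- expand_regimen(soc_regimen(), cst)
  ref <- r_euler_reference(th, ev, cst)
  tr <- simulate_trajectory(th, ev, cst)
  expect_equal(tr$times, ref$times)
  expect_equal(tr$cells, ref$cells, tolerance = 1e-12)
})

test_that("treated trajectories never exceed untreated ones", {
  th <- case_study_patients()$p2
  untreated <- simulate_trajectory(th)
  treated <- simulate_trajectory(th, expand_regimen(soc_regimen()))
  expect_true(all(treated$cells <= untreated$cells + 1e-9))
})

test_that("raising any single weekly dose never increases the final burden", {
  th <- case_study_patients()$p3
  base <- rep(2, 6)
  n_end <- function(u) {
    tr <- simulate_trajectory(th, expand_regimen(treatment_regimen(u)))
    tr$cells[length(tr$cells)]
  }
  n0 <- n_end(base)
  for (w in 1:6) {
    up <- base
    up[w] <- 6
    expect_lte(n_end(up), n0 + 1e-9)
  }
})

test_that("ensemble simulation is element-wise identical to single runs", {
  ths <- case_study_patients()
  m <- do.call(rbind, lapply(ths, function(t)
    c(rho = t$rho, K = t$K, N_initial = t$N_initial, alpha_RT = t$alpha_RT)))
  ens <- simulate_ensemble(m, soc_regimen())
  for (i in seq_along(ths)) {
    single <- simulate_trajectory(ths[[i]], treatment_events(soc_regimen()))
    expect_identical(ens[, i], single$cells)
  }
  # duplicated draws give identical columns
  dup <- simulate_ensemble(m[c(1, 1), ], soc_regimen())
  expect_identical(dup[, 1], dup[, 2])
})

test_that("trajectories stay within physical bounds", {
  set.seed(42)
  cohort <- sample_cohort(default_prior(), 20, seed = 42)
  ens <- simulate_ensemble(cohort, soc_regimen())
  expect_true(all(ens >= 0))
  K <- vapply(cohort, `[[`, numeric(1), "K")
  expect_true(all(t(ens) <= K * (1 + 1e-6)))
})

test_that("parameter validation enforces positivity and N_initial < K", {
  expect_error(tumor_parameters(-0.1, 1e11, 1e10, 0.05), "rho")
  expect_error(tumor_parameters(0.1, 1e11, 2e11, 0.05), "carrying capacity")
  expect_error(tumor_parameters(0.1, 1e11, 1e10, 0), "alpha_RT")
})

test_that("trajectory CSV export round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  th <- tumor_parameters(0.09, 1e11, 1.9e10, 0.05)
  tr <- simulate_trajectory(th)
  write_trajectory_csv(tr, tmp)
  back <- read.csv(tmp)
  expect_equal(back$time_days, tr$times)
  expect_equal(back$cells, tr$cells)
})
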