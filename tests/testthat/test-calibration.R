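test_that("Step-1 initial-burden update builds the right truncated normal", {
  s <- initial_burden_update(1.9e10, 2e9)
  expect_equal(s$mu, 1.9e10)
  expect_equal(s$sigma, 2e9)
  expect_equal(s$lower, 1.5e10)
  expect_equal(s$upper, 2.3e10)
  # lower bound clamps at zero
  s2 <- initial_burden_update(1e9, 2e9)
  expect_equal(s2$lower, 0)
  s3 <- initial_burden_update(0, 2e9)
  expect_equal(c(s3$mu, s3$lower, s3$upper), c(0, 0, 4e9))
})

test_that("log-likelihood peaks at the model value, adds over observations, and normalizes", {
  th <- case_study_patients()$p2
  cst <- fixed_constants()
  tr <- simulate_trajectory(th, treatment_events(soc_regimen()), cst,
                            t_end = 27)
  mu <- tr$cells[tr$times %in% c(20, 27)]
  obs_exact <- observation_set(c(20, 27), mu, sigma = 2e9)
  ll_exact <- log_likelihood(th, obs_exact)
  # any perturbed observation has lower likelihood (mode of the density)
  for (shift in c(-3e9, 1e9, 5e9)) {
    obs_shift <- observation_set(c(20, 27), pmax(mu + shift, 0), 2e9)
    expect_lt(log_likelihood(th, obs_shift), ll_exact)
  }
  # additivity over observations: the joint log-likelihood is the sum of the
  # per-observation ones
  v <- mu + c(1e9, -5e8)
  ll_joint <- log_likelihood(th, observation_set(c(20, 27), v, 2e9))
  ll_parts <- log_likelihood(th, observation_set(20, v[1], 2e9)) +
    log_likelihood(th, observation_set(27, v[2], 2e9))
  expect_equal(ll_joint, ll_parts, tolerance = 1e-10)
  # the observation density integrates to one over o >= 0
  # (integrated in units of sigma so quadrature sees the peak)
  m <- 3e9  # mean within a few sigma of the truncation point
  sg <- 2e9
  total <- integrate(function(z)
    sg * exp(gliotwin:::obs_log_density(z * sg, m, sg)), 0, 20)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("calibration validates its inputs", {
  obs_no_day0 <- observation_set(c(20, 27), c(2e10, 1.5e10))
  expect_error(calibrate(obs_no_day0, settings = test_mcmc()), "day-0")
  obs_no_rt <- observation_set(c(0, 20), c(2e10, 5e10))
  expect_error(calibrate(obs_no_rt, settings = test_mcmc()),
               "after the start of RT")
})

test_that("calibration recovers a synthetic patient from low-noise data", {
  th <- case_study_patients()$p2
  sigma <- 2e8  # a tenth of the nominal noise
  obs <- generate_observations(th, sigma = sigma, seed = 42)
  post <- calibrate(obs, settings = test_mcmc(seed = 42))
  truth <- unlist(unclass(th))
  pm <- colMeans(post$draws)
  ps <- apply(post$draws, 2, sd)
  for (nm in names(truth))
    expect_lt(abs(pm[nm] - truth[nm]), 2 * ps[nm] + 1e-12)
  # uncertainty shrinks relative to the prior scale
  prior <- default_prior()
  for (nm in names(truth))
    expect_lt(ps[nm], prior[[nm]]$sigma)
  # draws never violate the truncation bounds
  for (nm in c("rho", "K", "alpha_RT")) {
    expect_gte(min(post$draws[, nm]), prior[[nm]]$lower)
    expect_lte(max(post$draws[, nm]), prior[[nm]]$upper)
  }
  n_spec <- initial_burden_update(obs$values[obs$times == 0][1], sigma)
  expect_gte(min(post$draws[, "N_initial"]), n_spec$lower)
  expect_lte(max(post$draws[, "N_initial"]), n_spec$upper)
  expect_true(all(post$diagnostics$rhat < 1.01))
})

test_that("calibration is reproducible under a fixed seed", {
  th <- case_study_patients()$p3
  obs <- generate_observations(th, seed = 7)
  p1 <- calibrate(obs, settings = test_mcmc(seed = 7, draws = 600))
  p2 <- calibrate(obs, settings = test_mcmc(seed = 7, draws = 600))
  expect_identical(p1$draws, p2$draws)
})

test_that("posterior predictive bands behave correctly", {
  th <- case_study_patients()$p1
  obs <- generate_observations(th, seed = 3)
  post <- calibrate(obs, settings = test_mcmc(seed = 3))
  # singleton ensemble: min = median = max
  pp1 <- posterior_predictive(post, n = 1, seed = 1)
  expect_equal(pp1$bands$min, pp1$bands$median)
  expect_equal(pp1$bands$median, pp1$bands$max)
  # observations fall inside the min-max band
  pp <- posterior_predictive(post, n = 500, seed = 1)
  idx <- match(obs$times, pp$times)
  expect_true(all(obs$values >= pp$bands$min[idx] - 1e-6))
  expect_true(all(obs$values <= pp$bands$max[idx] + 1e-6))
  # posterior band at the horizon is no wider than the prior band
  set.seed(9)
  prior_draws <- do.call(rbind, lapply(sample_cohort(n_p = 500, seed = 9),
                                       unlist))
  pp_prior <- posterior_predictive(prior_draws, n = 500, seed = 1)
  last <- length(pp$times)
  post_width <- pp$bands$max[last] - pp$bands$min[last]
  prior_width <- pp_prior$bands$max[last] - pp_prior$bands$min[last]
  expect_lte(post_width, prior_width)
})

test_that("posterior export writes draws CSV and diagnostics JSON", {
  th <- case_study_patients()$p2
  obs <- generate_observations(th, seed = 8)
  post <- calibrate(obs, settings = test_mcmc(seed = 8, draws = 600))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(post, tmp)
  back <- read.csv(tmp)
  expect_named(back, c("rho", "K", "N_initial", "alpha_RT"))
  expect_equal(nrow(back), nrow(post$draws))
  diag <- jsonlite::read_json(paste0(tmp, ".diagnostics.json"),
                              simplifyVector = TRUE)
  expect_true(all(diag$diagnostics$rhat < 1.05))
})
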