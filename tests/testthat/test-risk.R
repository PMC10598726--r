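test_that("a controlled tumor is censored at the 132-day TTP cap", {
  th <- tumor_parameters(0.007, 1e11, 1.9e10, alpha_RT = 0.1)
  res <- time_to_progression(th, soc_regimen())
  expect_equal(res$ttp, 132)
  expect_true(res$censored)
})

test_that("with no treatment effect and monotone growth TTP is the first grid step after RT", {
  # S_C = 1 and negligible radiosensitivity: the trajectory is monotone, so
  # the burden exceeds its day-20 value at the first grid time after day 62
  cst <- fixed_constants(S_C = 1)
  th <- tumor_parameters(0.2, 1e11, 1.9e10, alpha_RT = 1e-12)
  res <- time_to_progression(th, treatment_regimen(rep(0, 6)), cst)
  expect_equal(res$ttp, 42.2)
  expect_false(res$censored)
  expect_equal(res$threshold_cells, closed_form_logistic(th, 20),
               tolerance = 5e-3)
})

test_that("TTP is deterministic and matches a brute-force trajectory scan", {
  cst <- fixed_constants()
  th <- case_study_patients()$p3
  res1 <- time_to_progression(th, soc_regimen(), cst)
  res2 <- time_to_progression(th, soc_regimen(), cst)
  expect_identical(res1, res2)
  # brute force on the stored trajectory
  tr <- simulate_trajectory(th, treatment_events(soc_regimen(), cst), cst)
  nth <- tr$cells[tr$times == cst$rt_start_day]
  hit <- which(tr$times > cst$t_post_rt & tr$cells > nth)
  expected <- if (length(hit)) tr$times[hit[1]] - 20 else 132
  expect_equal(res1$ttp, expected)
  expect_equal(res1$threshold_cells, nth)
})

test_that("QoI samples are negated TTPs, order-preserving, within [-132, 0)", {
  set.seed(21)
  cohort <- sample_cohort(n_p = 30, seed = 21)
  q <- qoi_samples(cohort, soc_regimen())
  loop <- -vapply(cohort, function(t)
    time_to_progression(t, soc_regimen())$ttp, numeric(1))
  expect_equal(q, loop)
  expect_true(all(q >= -132 & q < 0))
})

test_that("empirical quantile uses the upper order-statistic convention", {
  expect_equal(empirical_quantile(sample(1:100), 0.95), 95)
  expect_equal(empirical_quantile(rep(3.5, 40), 0.2), 3.5)
  expect_equal(empirical_quantile(c(5, 1, 9), 0.999), 9)
  expect_error(empirical_quantile(numeric(0), 0.95), "empty")
})

test_that("superquantile of 1..100 at 0.95 equals the mean of the top five", {
  expect_equal(superquantile(sample(1:100), 0.95), mean(96:100))  # 98
  expect_equal(superquantile(rep(7, 10), 0.5), 7)
})

test_that("superquantile of Uniform(0,1) tends to (1+alpha)/2", {
  set.seed(5)
  u <- runif(1e5)
  expect_equal(superquantile(u, 0.95), 0.975, tolerance = 0.005)
})

test_that("superquantile properties hold on random samples", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(200, sd = runif(1, 0.5, 5))
    a <- runif(1, 0.05, 0.95)
    q <- empirical_quantile(x, a)
    sq <- superquantile(x, a)
    expect_gte(sq, q)
    # non-decreasing in alpha
    expect_gte(superquantile(x, min(a + 0.03, 0.99)), sq - 1e-12)
    # translation equivariance and positive homogeneity
    expect_equal(superquantile(x + 3, a), sq + 3, tolerance = 1e-12)
    expect_equal(superquantile(2.5 * x, a), 2.5 * sq, tolerance = 1e-12)
  }
})

test_that("plug-in superquantile equals the tail mean when (1-alpha)n is integral", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 100
    x <- rnorm(n)
    a <- sample(c(0.9, 0.95, 0.8), 1)
    k <- round((1 - a) * n)
    expect_equal(superquantile(x, a), mean(sort(x, decreasing = TRUE)[1:k]),
                 tolerance = 1e-12)
  }
})

test_that("TTP superquantile is the negated superquantile of the QoI and is conservative", {
  set.seed(23)
  draws <- do.call(rbind, lapply(sample_cohort(n_p = 100, seed = 23),
                                 function(t) unlist(t)))
  sq <- ttp_superquantile(draws, soc_regimen(), risk_spec(0.95),
                          n_MC = nrow(draws))
  q <- qoi_samples(draws, soc_regimen())
  expect_equal(sq, -superquantile(q, 0.95))
  ttp <- -q
  expect_lte(sq, median(ttp))       # conservative lower-tail summary
  # fully controlled ensemble sits at the cap
  ctrl <- matrix(rep(c(0.007, 1e11, 1.9e10, 0.1), each = 50), ncol = 4,
                 dimnames = list(NULL, c("rho", "K", "N_initial", "alpha_RT")))
  expect_equal(ttp_superquantile(ctrl, soc_regimen(), n_MC = 50), 132)
})

test_that("TTP sample sets export one CSV column per regimen", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  sets <- list(SOC = c(40, 132, 90), `OUU:60 Gy` = c(55, 132, 101))
  write_ttp_samples_csv(sets, tmp)
  back <- read.csv(tmp, check.names = FALSE)
  expect_equal(names(back), c("SOC", "OUU:60 Gy"))
  expect_equal(back$SOC, sets$SOC)
})

test_that("per-theta TTP is non-decreasing when any weekly dose is raised", {
  th <- case_study_patients()$p2
  base <- rep(2, 6)
  t0 <- time_to_progression(th, treatment_regimen(base))$ttp
  for (w in 2:6) {
    up <- base
    up[w] <- 7
    expect_gte(time_to_progression(th, treatment_regimen(up))$ttp, t0)
  }
})
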