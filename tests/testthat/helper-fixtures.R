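# Case-study patients (ground-truth parameter sets used throughout the tests)
case_study_patients <- function() {
  list(
    p1 = tumor_parameters(rho = 1.14e-1, K = 1.17e11, N_initial = 1.54e10,
                          alpha_RT = 1.05e-3),
    p2 = tumor_parameters(rho = 1.09e-1, K = 1.09e11, N_initial = 2.60e10,
                          alpha_RT = 4.58e-2),
    p3 = tumor_parameters(rho = 2.25e-1, K = 1.40e11, N_initial = 2.62e10,
                          alpha_RT = 3.90e-2)
  )
}

# Small-but-converging MCMC settings for unit tests
test_mcmc <- function(seed = 1L, draws = 3000L) {
  mcmc_settings(chains = 4, draws_per_chain = draws, retained = 2 * draws,
                warmup = 20000, thin = 24, seed = seed)
}

# Plain-R forward Euler with treatment events: independent reference for the
# compiled integrator (same recording convention: pre-event state stored).
r_euler_reference <- function(theta, events, constants,
                              t_end = constants$t_finite) {
  dt <- constants$dt
  times <- seq(0, t_end, by = dt)
  cells <- numeric(length(times))
  N <- theta$N_initial
  ev <- setNames(rep(NA_integer_, 0), NULL)
  for (j in seq_along(times)) {
    cells[j] <- N
    if (j == length(times)) break
    t <- times[j]
    k <- which(!is.na(match(events$day, t)) & abs(events$day - t) < 1e-9)
    if (length(k) == 1) {
      N <- N * surviving_fraction(events$rt_dose_gy[k], theta$alpha_RT,
                                  constants, events$chemo[k])
    }
    N <- N + dt * theta$rho * N * (1 - N / theta$K)
  }
  list(times = times, cells = cells)
}
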