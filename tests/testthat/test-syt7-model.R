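test_that("calcium waveform reproduces peak, residual decay and superposition", {
  params <- ca_waveform_params()
  stim1 <- stim_train(0.001)
  grid <- two_timescale_grid(stim1, 0.1)
  ca <- build_ca_waveform(params, stim1, grid)
  # at the Gaussian centre: local peak plus the residual contribution
  at_peak <- ca[which.min(abs(grid - (0.001 + 0.25e-3)))]
  resid_at_peak <- exp(-0.25e-3 / 50e-3)
  expect_equal(at_peak, 40 + resid_at_peak, tolerance = 1e-3)
  # one residual time constant after the AP: 1/e uM (local part negligible)
  at_tau <- ca[which.min(abs(grid - (0.001 + 50e-3)))]
  expect_equal(at_tau, exp(-1), tolerance = 1e-3)
  # two APs 25 ms apart: residuals superpose linearly
  stim2 <- stim_train(c(0.001, 0.026))
  grid2 <- two_timescale_grid(stim2, 0.1)
  ca2 <- build_ca_waveform(params, stim2, grid2)
  t_probe <- 0.026 + 2e-3  # past the local transient of the 2nd AP
  at_probe <- ca2[which.min(abs(grid2 - t_probe))]
  expect_equal(at_probe,
               exp(-(t_probe - 0.001) / 0.05) + exp(-2e-3 / 0.05),
               tolerance = 1e-3)
  # a coarse grid cannot resolve the 85-us Gaussian
  expect_error(build_ca_waveform(params, stim1, seq(0, 0.1, by = 1e-3)),
               "too coarse")
})

test_that("binding chain conserves probability and stays at S0 without calcium", {
  syt7 <- syt7_params()
  times <- seq(0, 0.5, by = 1e-4)
  traj <- integrate_binding_chain(syt7, rep(0, length(times)), times)
  expect_true(all(traj[, "S0"] == 1))
  stim <- regular_train(40, 10, start = 1e-3)
  grid <- two_timescale_grid(stim, 0.3)
  ca <- build_ca_waveform(ca_waveform_params(), stim, grid)
  traj2 <- integrate_binding_chain(syt7, ca, grid)
  expect_lt(max(abs(rowSums(traj2) - 1)), 1e-9)
  expect_true(all(traj2 >= -1e-12))
  expect_error(integrate_binding_chain(syt7, rep(-1, length(times)),
                                       times), "negative")
})

test_that("without cooperativity the chain equilibrates to the binomial law", {
  syt7 <- syt7_params(n_ca_sites = 4, coop_b = 1)
  ca_const <- 1  # uM
  times <- seq(0, 3, by = 1e-4)
  traj <- integrate_binding_chain(syt7, rep(ca_const, length(times)),
                                  times)
  kd <- syt7$k_off / syt7$k_on  # 10/7 uM
  expect_equal(unname(traj[length(times), ]),
               dbinom(0:4, 4, ca_const / (ca_const + kd)),
               tolerance = 1e-5)
})

test_that("k1(t) follows the fully bound fraction", {
  syt7 <- syt7_params()
  traj <- matrix(0, 3, 6)
  traj[, 6] <- c(0, 0.5, 1)
  expect_equal(k1_of_t(traj, syt7), c(6.9, 156.9, 306.9))
  # monotone in the fully bound fraction
  expect_true(all(diff(k1_of_t(traj, syt7)) >= 0))
})

test_that("knockdown mode depresses monotonically; zero K1_max reduces to the constant-rate pool", {
  pool <- baseline_pool()
  syt7 <- syt7_params()
  ca <- ca_waveform_params()
  kd <- simulate_stp(pool, syt7, ca, 40, 20, kd_mode = TRUE)
  expect_true(all(diff(kd$normalized_amplitudes) <= 1e-9))
  degen <- simulate_stp(pool, syt7_params(K1_max = 0), ca, 20, 10)
  plain <- integrate_deterministic(pool, regular_train(20, 10,
                                                       start = 1e-3),
                                   times = degen$times)
  expect_equal(degen$normalized_amplitudes, plain$normalized_amplitudes,
               tolerance = 1e-12)
})

test_that("wild-type 40 Hz train shows depression then delayed facilitation", {
  sim <- simulate_stp(baseline_pool(), syt7_params(),
                      ca_waveform_params(), 40, 20)
  amps <- sim$normalized_amplitudes
  expect_lt(amps[2], 1)
  expect_gt(max(amps[-(1:2)]), 1)
})

test_that("fitted facilitation rate increases with stimulation frequency", {
  ks <- sapply(c(5, 10, 20, 40), function(f) {
    sim <- simulate_stp(baseline_pool(), syt7_params(),
                        ca_waveform_params(), f, 20)
    fit_kstf(sim$normalized_amplitudes, sim$ap_times)$k_stf
  })
  expect_true(all(diff(ks) > 0))
})

test_that("two-timescale integration agrees with a uniformly fine grid within 1%", {
  pool <- baseline_pool()
  syt7 <- syt7_params()
  caw <- ca_waveform_params()
  stim <- regular_train(40, 3, start = 1e-3)
  t_end <- max(stim$ap_times) + 20e-3
  run_on <- function(grid) {
    ca <- build_ca_waveform(caw, stim, grid)
    k1 <- k1_of_t(integrate_binding_chain(syt7, ca, grid), syt7)
    integrate_deterministic(pool, stim, times = grid,
                            k1_series = k1)$released_per_ap
  }
  coarse <- run_on(two_timescale_grid(stim, t_end))
  fine <- run_on(sort(unique(c(seq(0, t_end, by = 1e-6),
                               stim$ap_times))))
  expect_lt(max(abs(coarse / fine - 1)), 0.01)
})
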