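test_that("steady-state occupancy is k1/(k1+b1) and errors when undefined", {
  expect_equal(steady_state_occupancy(6.9, 16.1), 0.3)
  expect_equal(steady_state_occupancy(0, 5), 0)
  expect_equal(steady_state_occupancy(7, 7), 0.5)
  expect_error(steady_state_occupancy(0, 0), "undefined")
})

test_that("rate decomposition inverts the occupancy/relaxation pair", {
  r <- decompose_rates(0.3, 23)
  expect_equal(r$k1, 6.9)
  expect_equal(r$b1, 16.1)
  expect_equal(steady_state_occupancy(r$k1, r$b1), 0.3)
})

test_that("occupancy is constant at steady state without APs", {
  traj <- integrate_deterministic(baseline_pool(), stim_train(numeric(0)),
                                  dt = 1e-3, t_end = 0.5)
  expect_true(all(abs(traj$occupancy - 0.3) < 1e-12))
})

test_that("paired-pulse ratio after full depletion matches the closed-form relaxation", {
  # with p_v = 1 the pool empties at AP1 and refills toward p_occ with
  # rate k1 + b1 = 23/s, so PPR = 1 - exp(-23 * 0.02)
  stim <- stim_train(c(0, 0.02))
  expected <- 1 - exp(-23 * 0.02)
  fine <- integrate_deterministic(baseline_pool(), stim, dt = 1e-5)
  expect_equal(fine$normalized_amplitudes[2], expected, tolerance = 1e-4)
  default <- integrate_deterministic(baseline_pool(), stim, dt = 1e-3)
  expect_equal(default$normalized_amplitudes[2], expected,
               tolerance = 0.015)
})

test_that("a constant-rate refilling model never facilitates", {
  traj <- integrate_deterministic(baseline_pool(), regular_train(5, 20))
  expect_true(all(traj$normalized_amplitudes <= 1 + 1e-12))
  expect_equal(traj$normalized_amplitudes[1], 1)
  expect_true(all(traj$released_per_ap >= 0))
})

test_that("with p_v = 0 the occupancy relaxes mono-exponentially at rate k1+b1", {
  pool <- baseline_pool(p_v = 0)
  traj <- integrate_deterministic(pool, stim_train(numeric(0)),
                                  dt = 1e-5, t_end = 0.3,
                                  init_occupancy = 0)
  expected <- 0.3 * (1 - exp(-23 * traj$times))
  err_h <- max(abs(traj$occupancy - expected))
  expect_lt(err_h, 2e-5)  # first-order global error bound at dt = 1e-5
  half <- integrate_deterministic(pool, stim_train(numeric(0)),
                                  dt = 5e-6, t_end = 0.3,
                                  init_occupancy = 0)
  err_h2 <- max(abs(half$occupancy -
                      0.3 * (1 - exp(-23 * half$times))))
  expect_lt(err_h2, 0.6 * err_h)  # error halves with the step: first order
})

test_that("occupancy stays within [0,1] for random rates below the stability bound", {
  set.seed(11)
  for (i in 1:20) {
    k1 <- runif(1, 0, 50)
    b1 <- runif(1, 0, 50)
    dt <- 0.5 / max(k1 + b1, 1)
    pool <- pool_params(5, k1, b1, runif(1))
    traj <- integrate_deterministic(pool, regular_train(5, 5),
                                    dt = min(dt, 0.05),
                                    init_occupancy = runif(1))
    expect_true(all(traj$occupancy >= 0 & traj$occupancy <= 1))
  }
})

test_that("halving the Euler step changes per-AP amplitudes by < 0.5% at 1 ms", {
  stim <- regular_train(20, 20)
  a1 <- integrate_deterministic(baseline_pool(), stim, dt = 1e-3)
  a2 <- integrate_deterministic(baseline_pool(), stim, dt = 5e-4)
  expect_lt(max(abs(a1$normalized_amplitudes / a2$normalized_amplitudes
                    - 1)), 0.005)
})

test_that("dt larger than the smallest inter-AP interval is rejected", {
  expect_error(integrate_deterministic(baseline_pool(),
                                       regular_train(40, 5), dt = 0.05),
               "inter-AP")
})

test_that("stochastic simulation is reproducible and dialect-checked", {
  pool <- baseline_pool()
  stim <- stim_train(c(0, 0.02))
  a <- simulate_stochastic(pool, stim, 50, seed = 3)
  b <- simulate_stochastic(pool, stim, 50, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_stochastic(pool, stim, 10, seed = 1,
                                   dialect = "bogus"))
})

test_that("stochastic mean tracks the deterministic solution (3 SE)", {
  pool <- baseline_pool()
  stim <- stim_train(seq(0, 0.08, by = 0.02))
  n <- 1e5
  sim <- simulate_stochastic(pool, stim, n, seed = 21)
  det <- integrate_deterministic(pool, stim, dt = 1e-5)
  for (a in seq_along(stim$ap_times)) {
    x <- sim$quanta_released[sim$ap_index == a]
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - det$released_per_ap[a]), 3 * se)
  }
})

test_that("first-pulse failure frequency matches the binomial closed form", {
  pool <- baseline_pool()
  n <- 1e5
  sim <- simulate_stochastic(pool, stim_train(0), n, seed = 5)
  p_fail <- mean(sim$quanta_released == 0)
  expected <- (1 - 0.3)^6
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p_fail - expected), 3 * se)
})
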