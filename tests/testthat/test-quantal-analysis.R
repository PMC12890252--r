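test_that("MPFA parabola has the right values, roots and concavity", {
  expect_equal(mpfa_variance(0, 25, 5.3, 0.2), 0)
  # p = 1: only intra-site quantal variance remains
  expect_equal(mpfa_variance(5.3 * 25, 25, 5.3, 0.2),
               5.3 * 25^2 * 0.2^2)
  # direct evaluation at the fitted parameters of these synapses
  expect_equal(mpfa_variance(42.4, 25, 5.3, 0.2),
               25 * 42.4 * 1.04 - 42.4^2 / 5.3)
  expect_error(mpfa_variance(200, 25, 5.3, 0.2), "exceeds")
  # concave with roots at 0 and N q (1 + cv^2); without intra-site
  # variability the upper root sits at the maximal mean N q
  expect_equal(mpfa_variance(5.3 * 25, 25, 5.3, cv_qs = 0), 0,
               tolerance = 1e-9)
  m <- seq(1, 5.3 * 25 - 1, length.out = 50)
  expect_true(all(mpfa_variance(m, 25, 5.3, 0.2) > 0))
  expect_true(all(diff(mpfa_variance(m, 25, 5.3, 0.2), differences = 2)
                  < 0))
})

test_that("noise-free variance-mean points are recovered exactly", {
  m <- c(10, 30, 60, 90, 120)
  pts <- data.frame(mean_amp = m,
                    var_amp = mpfa_variance(m, 25, 5.3, 0.2))
  fit <- fit_mpfa(pts, cv_qs = 0.2, first_pulse_mean = 0.32 * 5.3 * 25)
  expect_equal(fit$n_sites, 5.3, tolerance = 1e-10)
  expect_equal(fit$q, 25, tolerance = 1e-10)
  expect_equal(fit$pr_first, 0.32, tolerance = 1e-10)
})

test_that("points on the rising limb only leave N unidentifiable", {
  m <- c(1, 2, 3, 4)  # p << 1: essentially linear
  pts <- data.frame(mean_amp = m,
                    var_amp = 25 * m * 1.04)  # zero curvature
  expect_error(fit_mpfa(pts), "unidentifiable|curvature")
  expect_error(fit_mpfa(data.frame(mean_amp = c(5, 5, 5),
                                   var_amp = c(1, 2, 3))), "distinct")
})

test_that("MPFA recovers generator parameters from stochastic trains", {
  # occupancy swept via k1 at fixed b1; p_v = 1 so p = p_occ
  occs <- seq(0.1, 0.9, by = 0.1)
  n_trials <- 100
  pts <- do.call(rbind, lapply(seq_along(occs), function(i) {
    pool <- pool_at_occupancy(5, 10, occs[i], p_v = 1)
    cfg <- synth_epsc_config(pool, stim_train(0), q = 25, cv_qs = 0.2,
                             noise_sd = 0, n_trials = n_trials,
                             seed = 100 + i)
    amp <- gen_epsc_trains(cfg)$amplitudes$amp_pA
    data.frame(mean_amp = mean(amp), var_amp = stats::var(amp))
  }))
  fit <- fit_mpfa(pts, cv_qs = 0.2)
  expect_equal(fit$n_sites, 5, tolerance = 0.15)
  expect_equal(fit$q, 25, tolerance = 0.15)
  # low-bias recovery with many trials at fewer probability points
  pts2 <- do.call(rbind, lapply(1:5, function(i) {
    occ <- c(0.15, 0.3, 0.5, 0.7, 0.85)[i]
    pool <- pool_at_occupancy(5, 10, occ, p_v = 1)
    cfg <- synth_epsc_config(pool, stim_train(0), q = 25, cv_qs = 0.2,
                             noise_sd = 0, n_trials = 1e4,
                             seed = 200 + i)
    amp <- gen_epsc_trains(cfg)$amplitudes$amp_pA
    data.frame(mean_amp = mean(amp), var_amp = stats::var(amp))
  }))
  fit2 <- fit_mpfa(pts2, cv_qs = 0.2)
  expect_equal(fit2$n_sites, 5, tolerance = 0.05)
  expect_equal(fit2$q, 25, tolerance = 0.05)
})

test_that("quantal size is read from the lowest-mean mixture component", {
  x <- gen_async_events(q = 24, cv = 0.25, n = 2000, seed = 31)
  fit <- fit_quantal_size(x)
  expect_equal(fit$q, 24, tolerance = 0.05)
  expect_equal(fit$cv, 0.25, tolerance = 0.2)
  # bimodal: single and double quanta -- report the first peak
  y <- c(gen_async_events(24, 0.15, 1500, seed = 32),
         gen_async_events(48, 0.15, 700, seed = 33))
  fit2 <- fit_quantal_size(y)
  expect_equal(fit2$n_components, 2)
  expect_equal(fit2$q, 24, tolerance = 0.05)
  expect_error(fit_quantal_size(numeric(0)), "too few")
  expect_error(fit_quantal_size(rnorm(10, 24, 2)), "too few")
})

test_that("train summaries: PPR, steady state, efficacy, scale invariance", {
  s <- summarize_train(rep(1, 20), frequency = 5)
  expect_equal(s$ppr, 1)
  expect_equal(s$epsc_ss, 1)
  expect_equal(s$efficacy, 5)
  # strong paired-pulse depression under slowed refilling
  amps <- c(1, 0.19, rep(0.3, 18))
  expect_equal(summarize_train(amps, 5)$ppr, 0.19)
  # rescaling raw amplitudes leaves the summary unchanged
  s1 <- summarize_train(amps * 137.5, 5)
  expect_equal(s1$ppr, 0.19)
  expect_equal(s1$epsc_ss, 0.3)
  # averaging identical trains changes nothing
  avg <- colMeans(matrix(rep(amps, 20), nrow = 20, byrow = TRUE))
  expect_equal(summarize_train(avg, 5)$ppr, 0.19)
  expect_error(summarize_train(1, 5), "too few")
})

test_that("facilitation rate constant is recovered from exponential sequences", {
  make <- function(k, a_ss, freq, n = 20) {
    t <- (0:(n - 1)) / freq
    list(t = t, a = a_ss - (a_ss - 1) * exp(-k * t))
  }
  s5 <- make(1.27, 3, 5)
  f5 <- fit_kstf(s5$a, s5$t)
  expect_equal(f5$k_stf, 1.27, tolerance = 0.02)
  s40 <- make(24.27, 2, 40)
  f40 <- fit_kstf(s40$a, s40$t)
  expect_equal(f40$k_stf, 24.27, tolerance = 0.05)
  flat <- fit_kstf(rep(1, 10), (0:9) / 5)
  expect_true(is.na(flat$k_stf))
  expect_equal(flat$a_ss, 1)
  expect_equal(flat$flag, "unidentifiable")
})
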