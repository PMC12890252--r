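#' Action-potential-locked calcium waveform parameters
#'
#' The presynaptic [Ca2+] seen by the replenishment sensor is modelled
#' as, for each AP, a brief local transient (Gaussian in time,
#' peak-scaled to `local_peak`) riding on a residual component that
#' decays mono-exponentially, plus an optional resting baseline.
#' Components superpose linearly across APs.
#'
#' All times are in seconds, concentrations in micromolar.
#'
#' @param local_peak Peak of the AP-local transient, uM (default 40).
#' @param local_tp Delay of the Gaussian centre after the AP, s
#'   (default 0.25 ms).
#' @param local_sigma Gaussian width sigma, s (default 0.085 ms,
#'   i.e. 0.2 ms full width at half maximum).
#' @param residual_amp Residual-calcium amplitude per AP, uM (default 1).
#' @param residual_tau Residual decay time constant, s (default 50 ms).
#' @param ca_rest Resting [Ca2+], uM (default 0; measured value 0.05).
#' @return An object of class `ca_waveform_params`.
#' @export
ca_waveform_params <- function(local_peak = 40, local_tp = 0.25e-3,
                               local_sigma = 0.085e-3, residual_amp = 1,
                               residual_tau = 50e-3, ca_rest = 0) {
  stopifnot(local_peak >= 0, local_tp >= 0, local_sigma > 0,
            residual_amp >= 0, residual_tau > 0, ca_rest >= 0)
  structure(
    list(local_peak = local_peak, local_tp = local_tp,
         local_sigma = local_sigma, residual_amp = residual_amp,
         residual_tau = residual_tau, ca_rest = ca_rest),
    class = "ca_waveform_params"
  )
}

#' Sequential calcium-binding parameters for synaptotagmin-7
#'
#' Syt7 binds up to `n_ca_sites` calcium ions sequentially:
#' `S_j -> S_{j+1}` at rate `(n - j) k_on [Ca]` and
#' `S_{j+1} -> S_j` at rate `(j + 1) k_off coop_b^j`, so the
#' cooperativity factor `coop_b < 1` slows successive unbinding
#' (positive cooperativity). The fully bound fraction drives the
#' docking rate: `k1(t) = k1_base + K1_max * S_n(t)`.
#'
#' @param n_ca_sites Number of sequential binding steps (default 5).
#' @param k_on Binding rate, 1/uM/s (default 7).
#' @param k_off Unbinding rate of the first bound ion, 1/s (default 10).
#' @param coop_b Cooperativity factor in (0, 1\] (default 0.35).
#' @param K1_max Maximal increment of the docking rate, 1/s (default 300).
#' @param k1_base Baseline docking rate, 1/s (default 6.9).
#' @return An object of class `syt7_params`.
#' @export
syt7_params <- function(n_ca_sites = 5, k_on = 7, k_off = 10,
                        coop_b = 0.35, K1_max = 300, k1_base = 6.9) {
  stopifnot(n_ca_sites >= 1, n_ca_sites == round(n_ca_sites),
            k_on >= 0, k_off >= 0, K1_max >= 0, k1_base >= 0,
            coop_b > 0)
  structure(
    list(n_ca_sites = as.integer(n_ca_sites), k_on = k_on, k_off = k_off,
         coop_b = coop_b, K1_max = K1_max, k1_base = k1_base),
    class = "syt7_params"
  )
}

#' Two-timescale integration grid for a stimulus train
#'
#' Fine steps (`dt_fine`) within `window` of each AP resolve the
#' sub-millisecond local calcium transient; coarse steps (`dt_coarse`)
#' cover the rest. AP times are grid points.
#'
#' @param stim A [stim_train()].
#' @param t_end End time, seconds.
#' @param dt_fine Fine step, s (default 5 us).
#' @param dt_coarse Coarse step, s (default 1 ms).
#' @param window Half-width of the fine window around each AP, s.
#' @return Increasing numeric vector of times.
#' @export
two_timescale_grid <- function(stim, t_end, dt_fine = 5e-6,
                               dt_coarse = 1e-3, window = 2e-3) {
  stopifnot(dt_fine > 0, dt_coarse >= dt_fine, t_end > 0)
  pts <- seq(0, t_end, by = dt_coarse)
  for (tap in stim$ap_times) {
    lo <- max(0, tap - window / 4)
    hi <- min(t_end, tap + window)
    pts <- c(pts, seq(lo, hi, by = dt_fine), tap)
  }
  sort(unique(pts))
}

#' Evaluate the calcium waveform on a time grid
#'
#' @param params A [ca_waveform_params()].
#' @param stim A [stim_train()].
#' @param times Time grid, seconds; must resolve the local transient
#'   (at least 5 samples per `local_sigma` around each AP).
#' @return Numeric vector of [Ca2+] in uM.
#' @export
build_ca_waveform <- function(params, stim, times) {
  stopifnot(all(diff(times) > 0))
  # the local Gaussian must be sampled finely enough near each AP
  for (tap in stim$ap_times) {
    win <- which(times >= tap & times <= tap + params$local_tp +
                   4 * params$local_sigma)
    if (length(win) < 2 ||
        max(diff(times[win])) > params$local_sigma / 5) {
      stop("time grid too coarse to resolve the local Ca transient; ",
           "use two_timescale_grid()")
    }
  }
  ca <- rep(params$ca_rest, length(times))
  for (tap in stim$ap_times) {
    ca <- ca + params$local_peak *
      exp(-((times - tap - params$local_tp)^2) /
            (2 * params$local_sigma^2))
    after <- times >= tap
    ca[after] <- ca[after] + params$residual_amp *
      exp(-(times[after] - tap) / params$residual_tau)
  }
  ca
}

# rate constants of the binding chain: forward (length n), backward (length n)
chain_rates <- function(params) {
  n <- params$n_ca_sites
  j <- 0:(n - 1)
  list(
    fwd_per_ca = (n - j) * params$k_on,          # S_j -> S_{j+1}, times [Ca]
    bwd = (j + 1) * params$k_off * params$coop_b^j  # S_{j+1} -> S_j
  )
}

#' Integrate the sequential calcium-binding chain
#'
#' Forward-Euler master-equation integration of the occupancy
#' distribution over `S_0 .. S_n` driven by a calcium concentration
#' series. Probability is conserved exactly by the update.
#'
#' @param params A [syt7_params()].
#' @param ca_series [Ca2+] in uM at each grid point.
#' @param times Time grid, seconds.
#' @param state0 Initial distribution over `S_0..S_n` (default: all
#'   probability in `S_0`).
#' @return Matrix (length(times) x (n+1)) of state fractions; column
#'   `j+1` is the fraction with `j` ions bound.
#' @export
integrate_binding_chain <- function(params, ca_series, times,
                                    state0 = NULL) {
  n <- params$n_ca_sites
  if (any(ca_series < 0)) stop("negative calcium concentration")
  nt <- length(times)
  stopifnot(length(ca_series) == nt)
  if (is.null(state0)) state0 <- c(1, rep(0, n))
  stopifnot(length(state0) == n + 1, all(state0 >= 0),
            abs(sum(state0) - 1) < 1e-9)
  r <- chain_rates(params)
  s <- state0
  out <- matrix(0, nt, n + 1)
  out[1, ] <- s
  for (i in seq_len(nt - 1)) {
    h <- times[i + 1] - times[i]
    flux <- r$fwd_per_ca * ca_series[i] * s[1:n] - r$bwd * s[2:(n + 1)]
    # net flux from S_j to S_{j+1}; antisymmetric update conserves sum
    ds <- c(-flux, 0) + c(0, flux)
    s <- s + h * ds
    out[i + 1, ] <- s
  }
  colnames(out) <- paste0("S", 0:n)
  out
}

#' Docking-rate time course from the binding-chain trajectory
#'
#' `k1(t) = k1_base + K1_max * (fraction of fully calcium-bound Syt7)`.
#'
#' @param state_traj Matrix returned by [integrate_binding_chain()].
#' @param params A [syt7_params()].
#' @return Numeric vector, 1/s.
#' @export
k1_of_t <- function(state_traj, params) {
  params$k1_base + params$K1_max * state_traj[, params$n_ca_sites + 1]
}

#' Simulate short-term plasticity with calcium-driven pool refilling
#'
#' Composes the calcium waveform, the Syt7 binding chain, the
#' time-dependent docking rate and the deterministic pool model for a
#' regular train, returning the baseline-normalized per-pulse
#' amplitudes. With `kd_mode = TRUE` the docking rate is frozen at
#' `k1_base` (the sensor-knockdown condition), leaving a pure
#' depletion-recovery model.
#'
#' @param pool A [pool_params()].
#' @param syt7 A [syt7_params()].
#' @param ca A [ca_waveform_params()].
#' @param frequency Stimulation frequency, Hz.
#' @param n_pulses Number of pulses (default 20).
#' @param kd_mode Freeze `k1` at baseline (default FALSE).
#' @param dt_fine,dt_coarse Grid steps for [two_timescale_grid()].
#' @return List of class `stp_simulation`: `times`, `ca`, `s_fractions`,
#'   `k1`, `occupancy`, `normalized_amplitudes`, `frequency`.
#' @export
simulate_stp <- function(pool, syt7, ca, frequency, n_pulses = 20,
                         kd_mode = FALSE, dt_fine = 5e-6,
                         dt_coarse = 1e-3) {
  stopifnot(frequency > 0)
  stim <- regular_train(frequency, n_pulses, start = dt_coarse)
  t_end <- max(stim$ap_times) + 50e-3
  grid <- two_timescale_grid(stim, t_end, dt_fine, dt_coarse)
  if (kd_mode || syt7$K1_max == 0) {
    ca_series <- NULL
    s_traj <- NULL
    k1 <- rep(syt7$k1_base, length(grid))
  } else {
    ca_series <- build_ca_waveform(ca, stim, grid)
    s_traj <- integrate_binding_chain(syt7, ca_series, grid)
    k1 <- k1_of_t(s_traj, syt7)
  }
  traj <- integrate_deterministic(pool, stim, times = grid,
                                  k1_series = k1)
  structure(
    list(times = grid, ca = ca_series, s_fractions = s_traj, k1 = k1,
         occupancy = traj$occupancy,
         released_per_ap = traj$released_per_ap,
         normalized_amplitudes = traj$normalized_amplitudes,
         ap_times = stim$ap_times, frequency = frequency,
         kd_mode = kd_mode),
    class = "stp_simulation"
  )
}
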