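#' Configuration for synthetic EPSC-train generation
#'
#' @param pool A [pool_params()].
#' @param stim A [stim_train()].
#' @param q Quantal size, pA (default 25).
#' @param cv_qs Intra-site quantal CV (default 0.2).
#' @param noise_sd Additive recording noise SD, pA.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return Object of class `synth_epsc_config`.
#' @export
synth_epsc_config <- function(pool, stim, q = 25, cv_qs = 0.2,
                              noise_sd = 0, n_trials, seed) {
  stopifnot(inherits(pool, "pool_params"), inherits(stim, "stim_train"),
            q > 0, cv_qs >= 0, noise_sd >= 0, n_trials >= 1)
  structure(
    list(pool = pool, stim = stim, q = q, cv_qs = cv_qs,
         noise_sd = noise_sd, n_trials = as.integer(n_trials),
         seed = as.integer(seed)),
    class = "synth_epsc_config"
  )
}

# exact draws from Normal(mu, sd) truncated at zero (inverse-CDF)
rtruncnorm0 <- function(n, mu, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mu, n))
  p0 <- stats::pnorm(0, mu, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mu, sd)
}

# quanta table -> amplitude table: each released quantum contributes a
# positive-truncated Normal(q, q*cv_qs) draw; additive recording noise
quanta_to_amps <- function(sim, q, cv_qs, noise_sd) {
  total <- sum(sim$quanta_released)
  draws <- rtruncnorm0(total, q, q * cv_qs)
  idx <- rep(seq_len(nrow(sim)), sim$quanta_released)
  amp <- numeric(nrow(sim))
  if (total > 0) {
    sums <- tapply(draws, factor(idx, levels = seq_len(nrow(sim))), sum)
    amp <- ifelse(is.na(sums), 0, as.numeric(sums))
  }
  amp + stats::rnorm(nrow(sim), 0, noise_sd)
}

#' Generate synthetic per-trial, per-pulse EPSC amplitudes
#'
#' Each trial simulates per-site occupancy (stochastic refilling
#' model), releases docked vesicles with probability `p_v` at each AP,
#' and sums positive-truncated Gaussian quantal amplitudes plus
#' additive recording noise.
#'
#' @param cfg A [synth_epsc_config()].
#' @param dialect Inter-AP propagation scheme, see
#'   [simulate_stochastic()]. The continuous-time dialect is the
#'   physically exact one and the default here.
#' @return List with `amplitudes` (data frame `trial`, `pulse_index`,
#'   `amp_pA`), `quanta` (the underlying release counts), and
#'   `ground_truth` (all generator parameters).
#' @export
gen_epsc_trains <- function(cfg, dialect = "continuous-time") {
  sim <- simulate_stochastic(cfg$pool, cfg$stim, cfg$n_trials,
                             seed = cfg$seed, dialect = dialect)
  amp <- quanta_to_amps(sim, cfg$q, cfg$cv_qs, cfg$noise_sd)
  list(
    amplitudes = data.frame(trial = sim$trial,
                            pulse_index = sim$ap_index,
                            amp_pA = amp),
    quanta = sim,
    ground_truth = list(
      n_sites = cfg$pool$n_sites, k1 = cfg$pool$k1_base,
      b1 = cfg$pool$b1, p_v = cfg$pool$p_v,
      p_occ = steady_state_occupancy(cfg$pool$k1_base, cfg$pool$b1),
      q = cfg$q, cv_qs = cfg$cv_qs, noise_sd = cfg$noise_sd,
      n_trials = cfg$n_trials, seed = cfg$seed, dialect = dialect)
  )
}

#' Generate paired-pulse success/failure trials
#'
#' Two-pulse version of [gen_epsc_trains()] that thresholds each
#' pulse's amplitude into success/failure. Defaults to the
#' one-transition-per-interval dialect, the scheme assumed by the
#' combinatorial failure analysis ([predict_joint()]).
#'
#' @param cfg A [synth_epsc_config()] whose stimulus has exactly two APs.
#' @param detection_threshold Amplitude above which a pulse counts as a
#'   success, pA (default `q / 2`).
#' @param dialect Inter-AP propagation scheme (default
#'   `"per-interval-BF"`).
#' @return List with `trials` (data frame `trial`, `s1`, `s2`),
#'   `observation` (a [failure_observation()] tallied from them), and
#'   `ground_truth`.
#' @export
gen_paired_trials <- function(cfg, detection_threshold = cfg$q / 2,
                              dialect = "per-interval-BF") {
  if (length(cfg$stim$ap_times) != 2) {
    stop("paired-trial generation needs a two-AP stimulus")
  }
  if (detection_threshold > cfg$pool$n_sites * cfg$q) {
    warning("detection threshold exceeds the maximal response: ",
            "all trials will be failures")
  }
  out <- gen_epsc_trains(cfg, dialect = dialect)
  a <- out$amplitudes
  s1 <- a$amp_pA[a$pulse_index == 1] > detection_threshold
  s2 <- a$amp_pA[a$pulse_index == 2] > detection_threshold
  trials <- data.frame(trial = seq_len(cfg$n_trials), s1 = s1, s2 = s2)
  isi <- diff(cfg$stim$ap_times)
  obs <- tally_failures(trials, cfg$pool$n_sites, isi)
  list(trials = trials, observation = obs,
       ground_truth = c(out$ground_truth,
                        list(detection_threshold = detection_threshold)))
}

#' Generate synthetic asynchronous-release event amplitudes
#'
#' Emulates the single-quantum amplitude list collected in a fixed
#' window after each stimulus under strontium: positive-truncated
#' Gaussian quanta plus additive detection noise.
#'
#' @param q Quantal size, pA.
#' @param cv Quantal CV.
#' @param n Number of events.
#' @param noise_sd Additive noise SD, pA (default 0).
#' @param seed Integer seed.
#' @return Numeric vector of event amplitudes, pA.
#' @export
gen_async_events <- function(q, cv, n, noise_sd = 0, seed) {
  stopifnot(q > 0, cv >= 0, n >= 1, noise_sd >= 0)
  set.seed(seed)
  rtruncnorm0(n, q, q * cv) + stats::rnorm(n, 0, noise_sd)
}

#' Configuration for synthetic two-channel line-scan generation
#'
#' Ground-truth buffering parameters default to the buffer-free
#' transient amplitude 1.16 uM, decay 43 ms and endogenous binding
#' ratio 96.4 estimated at these boutons (so `gamma = (1 + 96.4)/0.043`
#' per s and `delta_ca_total = 1.16 * (1 + 96.4)` uM).
#'
#' @param waveform A [ca_waveform_params()] (supplies `ca_rest`).
#' @param calib A [ratiometry_calib()].
#' @param indicator_total Indicator concentration, uM.
#' @param indicator_kd Indicator dissociation constant, uM (default 2.3).
#' @param kappa_s Endogenous static binding ratio (default 96.4).
#' @param a_ca Buffer-free transient amplitude, uM (default 1.16).
#' @param tau_ca Buffer-free decay time constant, s (default 0.043).
#' @param noise_cv Multiplicative channel noise CV (default 0).
#' @param n_sweeps Number of sweeps (default 3).
#' @param seed Integer seed.
#' @return Object of class `synth_linescan_config`.
#' @export
synth_linescan_config <- function(waveform, calib, indicator_total,
                                  indicator_kd = 2.3, kappa_s = 96.4,
                                  a_ca = 1.16, tau_ca = 0.043,
                                  noise_cv = 0, n_sweeps = 3, seed) {
  stopifnot(inherits(calib, "ratiometry_calib"), indicator_total > 0,
            indicator_kd > 0, kappa_s > 0, a_ca > 0, tau_ca > 0,
            noise_cv >= 0, n_sweeps >= 1)
  structure(
    list(waveform = waveform, calib = calib,
         indicator_total = indicator_total, indicator_kd = indicator_kd,
         kappa_s = kappa_s, a_ca = a_ca, tau_ca = tau_ca,
         gamma = (1 + kappa_s) / tau_ca,
         delta_ca_total = a_ca * (1 + kappa_s),
         noise_cv = noise_cv, n_sweeps = as.integer(n_sweeps),
         seed = as.integer(seed)),
    class = "synth_linescan_config"
  )
}

# self-consistent indicator binding ratio: kappa_B depends on the peak,
# which depends on kappa_B; a short fixed-point iteration converges
linescan_kappa_b <- function(cfg) {
  rest <- cfg$waveform$ca_rest
  kb <- kappa_b(cfg$indicator_total, cfg$indicator_kd, rest, rest)
  for (i in 1:50) {
    peak <- rest + cfg$delta_ca_total / (1 + cfg$kappa_s + kb)
    kb_new <- kappa_b(cfg$indicator_total, cfg$indicator_kd, rest, peak)
    if (abs(kb_new - kb) < 1e-12) break
    kb <- kb_new
  }
  kb
}

#' Generate a synthetic two-channel ratiometric line scan
#'
#' A single AP at `t = 0` elicits a calcium transient whose measured
#' amplitude and decay carry the buffering load of the indicator:
#' `A_obs = delta_ca_total / (1 + kappa_s + kappa_b)` and
#' `tau_obs = (1 + kappa_s + kappa_b) / gamma`, with `kappa_b`
#' computed self-consistently from the resting and peak calcium. The
#' calcium trace is mapped to a fluorescence ratio through the inverse
#' calibration and split into two channels with multiplicative noise.
#'
#' @param cfg A [synth_linescan_config()].
#' @param sample_rate Line rate, Hz (default 650).
#' @param t_pre Baseline before the AP, s (default 0.05).
#' @param t_post Duration after the AP, s (default 0.4).
#' @return List with `scan` (data frame `sweep`, `time_s`, `f_green`,
#'   `f_red`) and `ground_truth` (including the realised `kappa_b`,
#'   `a_obs`, `tau_obs`).
#' @export
gen_linescan <- function(cfg, sample_rate = 650, t_pre = 0.05,
                         t_post = 0.4) {
  set.seed(cfg$seed)
  kb <- linescan_kappa_b(cfg)
  rest <- cfg$waveform$ca_rest
  a_obs <- cfg$delta_ca_total / (1 + cfg$kappa_s + kb)
  tau_obs <- (1 + cfg$kappa_s + kb) / cfg$gamma
  # sampling aligned to the stimulus: t = 0 is a scan line, so the
  # peak sample sits at the transient onset
  times <- seq(-round(t_pre * sample_rate),
               round(t_post * sample_rate)) / sample_rate
  ca <- rest + ifelse(times >= 0, a_obs * exp(-times / tau_obs), 0)
  ratio <- ca_to_ratio(ca, cfg$calib)
  red_base <- 1000
  scans <- lapply(seq_len(cfg$n_sweeps), function(s) {
    f_red <- red_base *
      (1 + stats::rnorm(length(times), 0, cfg$noise_cv))
    f_green <- ratio * red_base *
      (1 + stats::rnorm(length(times), 0, cfg$noise_cv))
    data.frame(sweep = s, time_s = times, f_green = f_green,
               f_red = f_red)
  })
  list(
    scan = do.call(rbind, scans),
    ground_truth = list(
      kappa_s = cfg$kappa_s, a_ca = cfg$a_ca, tau_ca = cfg$tau_ca,
      gamma = cfg$gamma, delta_ca_total = cfg$delta_ca_total,
      kappa_b = kb, a_obs = a_obs, tau_obs = tau_obs,
      ca_rest = rest, indicator_total = cfg$indicator_total,
      indicator_kd = cfg$indicator_kd, seed = cfg$seed)
  )
}

#' Average a line scan across sweeps and fit the calcium transient
#'
#' Averages the per-sample fluorescence ratio over sweeps, converts it
#' to calcium through the calibration, and fits the transient with
#' [fit_transient()].
#'
#' @param scan Data frame with `sweep`, `time_s`, `f_green`, `f_red`.
#' @param calib A [ratiometry_calib()].
#' @return List with `time`, `ca`, and the [fit_transient()] result
#'   (`amplitude`, `tau`, `baseline`, `t_peak`).
#' @export
analyze_linescan <- function(scan, calib) {
  stopifnot(all(c("sweep", "time_s", "f_green", "f_red") %in%
                  names(scan)))
  ratio <- scan$f_green / scan$f_red
  mean_ratio <- tapply(ratio, scan$time_s, mean)
  times <- as.numeric(names(mean_ratio))
  o <- order(times)
  times <- times[o]
  ca <- ratio_to_ca(as.numeric(mean_ratio)[o], calib)
  fit <- fit_transient(times, ca)
  c(list(time = times, ca = ca), fit)
}
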