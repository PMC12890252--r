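#' Parameters of the one-step vesicle-pool refilling model
#'
#' A finite pool of `n_sites` independent release sites exchanges vesicles
#' with an unlimited reserve: empty sites are filled at forward rate
#' `k1_base` (per second) and docked vesicles undock at rate `b1` (per
#' second). Upon an action potential each docked vesicle fuses with
#' probability `p_v`. Occupancy relaxes toward `k1/(k1+b1)` with rate
#' `k1 + b1`.
#'
#' @param n_sites Number of release sites (positive integer).
#' @param k1_base Baseline forward docking rate, 1/s.
#' @param b1 Undocking rate, 1/s.
#' @param p_v Vesicular fusion probability per action potential, in \[0,1\].
#' @return An object of class `pool_params`.
#' @examples
#' pool_params(n_sites = 6, k1_base = 6.9, b1 = 16.1, p_v = 1)
#' @export
pool_params <- function(n_sites, k1_base, b1, p_v) {
  stopifnot(
    length(n_sites) == 1, n_sites >= 1, n_sites == round(n_sites),
    length(k1_base) == 1, k1_base >= 0,
    length(b1) == 1, b1 >= 0,
    length(p_v) == 1, p_v >= 0, p_v <= 1
  )
  structure(
    list(n_sites = as.integer(n_sites), k1_base = k1_base, b1 = b1, p_v = p_v),
    class = "pool_params"
  )
}

#' Stimulus train
#'
#' @param ap_times Strictly increasing action-potential times, seconds.
#' @param label Optional free-text label.
#' @return An object of class `stim_train`.
#' @export
stim_train <- function(ap_times, label = "") {
  ap_times <- as.numeric(ap_times)
  if (length(ap_times) > 0) {
    stopifnot(all(ap_times >= 0), all(diff(ap_times) > 0))
  }
  structure(list(ap_times = ap_times, label = label), class = "stim_train")
}

#' Regular stimulus train at a fixed frequency
#'
#' @param frequency Stimulation frequency, Hz.
#' @param n_pulses Number of pulses.
#' @param start Time of the first pulse, seconds.
#' @return A [stim_train()].
#' @export
regular_train <- function(frequency, n_pulses, start = 0) {
  stopifnot(frequency > 0, n_pulses >= 1)
  stim_train(start + (seq_len(n_pulses) - 1) / frequency,
             label = sprintf("%g Hz x %d", frequency, n_pulses))
}

#' Steady-state release-site occupancy
#'
#' Resting occupancy of the refilling model, `k1 / (k1 + b1)`.
#'
#' @param k1 Forward docking rate, 1/s.
#' @param b1 Undocking rate, 1/s.
#' @return Occupancy fraction in \[0,1\].
#' @examples
#' steady_state_occupancy(6.9, 16.1)  # 0.3
#' @export
steady_state_occupancy <- function(k1, b1) {
  stopifnot(k1 >= 0, b1 >= 0)
  if (any(k1 + b1 <= 0)) {
    stop("occupancy undefined: k1 + b1 must be positive")
  }
  k1 / (k1 + b1)
}

#' Split a relaxation rate into docking and undocking rates
#'
#' Given the resting occupancy and the occupancy relaxation rate
#' `k1 + b1`, returns the forward and reverse rates: `k1 = p_occ * total`,
#' `b1 = total - k1`.
#'
#' @param p_occ Resting occupancy in (0,1).
#' @param total_rate Relaxation rate `k1 + b1`, 1/s.
#' @return List with elements `k1` and `b1`.
#' @examples
#' decompose_rates(0.3, 23)  # k1 = 6.9, b1 = 16.1
#' @export
decompose_rates <- function(p_occ, total_rate) {
  stopifnot(p_occ > 0, p_occ < 1, total_rate > 0)
  k1 <- p_occ * total_rate
  list(k1 = k1, b1 = total_rate - k1)
}

# Build an integration grid containing every AP time. Uniform step `dt`
# unless an explicit (possibly nonuniform) grid is supplied.
build_grid <- function(stim, dt, t_end, times = NULL) {
  if (!is.null(times)) {
    stopifnot(all(diff(times) > 0))
    if (length(stim$ap_times) > 0 &&
        !all(stim$ap_times %in% times)) {
      stop("supplied time grid must contain every AP time")
    }
    return(times)
  }
  stopifnot(dt > 0)
  if (length(stim$ap_times) > 1 && dt > min(diff(stim$ap_times))) {
    stop("dt exceeds the smallest inter-AP interval")
  }
  if (is.null(t_end)) {
    t_end <- if (length(stim$ap_times) > 0) max(stim$ap_times) + 0.1 else 1
  }
  sort(unique(c(seq(0, t_end, by = dt), stim$ap_times)))
}

#' Deterministic (expected-value) integration of the refilling model
#'
#' Forward-Euler integration of the expected occupancy
#' `d rho/dt = k1 (1 - rho) - b1 rho`, with release as an instantaneous
#' multiplicative event: at each AP the occupancy is multiplied by
#' `1 - p_v` and the decrement times `n_sites` is recorded as the
#' expected number of released quanta.
#'
#' @param params A [pool_params()].
#' @param stim A [stim_train()].
#' @param dt Euler step, seconds (default 1 ms).
#' @param t_end End of integration, seconds (default: 100 ms past last AP).
#' @param k1_series Optional time-dependent forward rate, one value per
#'   grid point, overriding `params$k1_base`.
#' @param times Optional explicit (possibly nonuniform) time grid; must
#'   contain every AP time. Overrides `dt`/`t_end`.
#' @param init_occupancy Initial occupancy; defaults to the steady state
#'   of the baseline rates.
#' @return An object of class `pool_trajectory`: list with `times`,
#'   `occupancy`, `ap_times`, `released_per_ap`, `normalized_amplitudes`.
#' @export
integrate_deterministic <- function(params, stim, dt = 1e-3, t_end = NULL,
                                    k1_series = NULL, times = NULL,
                                    init_occupancy = NULL) {
  grid <- build_grid(stim, dt, t_end, times)
  nt <- length(grid)
  k1 <- if (is.null(k1_series)) rep(params$k1_base, nt) else k1_series
  if (length(k1) != nt) stop("k1_series must match the integration grid")
  b1 <- params$b1
  rho0 <- if (is.null(init_occupancy)) {
    steady_state_occupancy(params$k1_base, b1)
  } else init_occupancy
  stopifnot(rho0 >= 0, rho0 <= 1)

  ap_idx <- match(stim$ap_times, grid)
  is_ap <- logical(nt)
  is_ap[ap_idx] <- TRUE

  occ <- numeric(nt)
  released <- numeric(length(ap_idx))
  rho <- rho0
  j <- 0L
  for (i in seq_len(nt)) {
    if (is_ap[i]) {
      j <- j + 1L
      released[j] <- params$p_v * rho * params$n_sites
      rho <- rho * (1 - params$p_v)
    }
    occ[i] <- rho
    if (i < nt) {
      h <- grid[i + 1] - grid[i]
      rho <- rho + h * (k1[i] * (1 - rho) - b1 * rho)
    }
  }
  norm_amp <- if (length(released) > 0 && released[1] > 0) {
    released / released[1]
  } else {
    rep(NA_real_, length(released))
  }
  structure(
    list(times = grid, occupancy = occ, ap_times = stim$ap_times,
         released_per_ap = released, normalized_amplitudes = norm_amp),
    class = "pool_trajectory"
  )
}

#' @export
as.data.frame.pool_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, occupancy = x$occupancy)
}

#' Per-pulse amplitude table of a pool trajectory
#'
#' @param traj A `pool_trajectory`.
#' @return Data frame with `ap_index`, `ap_time_s`, `released`,
#'   `normalized_amplitude`.
#' @export
per_ap_table <- function(traj) {
  data.frame(
    ap_index = seq_along(traj$ap_times),
    ap_time_s = traj$ap_times,
    released = traj$released_per_ap,
    normalized_amplitude = traj$normalized_amplitudes
  )
}

#' Stochastic per-site simulation of the refilling model
#'
#' Simulates each release site as a two-state (empty/docked) process.
#' Two inter-AP propagation schemes are provided:
#' \describe{
#'   \item{`"continuous-time"`}{the exact two-state Markov propagator:
#'     a docked site is still docked after an interval of length `u`
#'     with probability `p_inf + (1 - p_inf) exp(-(k1+b1) u)` and an
#'     empty site is docked with probability `p_inf (1 - exp(-(k1+b1) u))`,
#'     where `p_inf = k1/(k1+b1)`.}
#'   \item{`"per-interval-BF"`}{at most one transition per interval:
#'     each initially-docked site undocks with probability
#'     `B = 1 - exp(-b1 u)` and each initially-empty site docks with
#'     probability `F = 1 - exp(-k1 u)`; sites vacated within the
#'     interval do not refill. This matches the combinatorial
#'     failure-pattern analysis (see [predict_joint()]).}
#' }
#' At each AP every docked vesicle releases independently with
#' probability `p_v`.
#'
#' @param params A [pool_params()].
#' @param stim A [stim_train()].
#' @param n_trials Number of independent trials.
#' @param seed Integer seed; runs with the same seed are identical.
#' @param dialect `"continuous-time"` or `"per-interval-BF"`.
#' @param init_occupancy Probability a site starts docked (default:
#'   steady state).
#' @return Data frame with columns `trial`, `ap_index`, `quanta_released`.
#' @export
simulate_stochastic <- function(params, stim, n_trials, seed,
                                dialect = c("continuous-time",
                                            "per-interval-BF"),
                                init_occupancy = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(n_trials >= 1)
  set.seed(seed)
  N <- params$n_sites
  k1 <- params$k1_base
  b1 <- params$b1
  p_inf <- steady_state_occupancy(k1, b1)
  rho0 <- if (is.null(init_occupancy)) p_inf else init_occupancy

  n_ap <- length(stim$ap_times)
  docked <- matrix(stats::runif(n_trials * N) < rho0, n_trials, N)
  out <- matrix(0L, n_trials, n_ap)
  for (a in seq_len(n_ap)) {
    fire <- docked & (matrix(stats::runif(n_trials * N), n_trials, N) <
                        params$p_v)
    out[, a] <- as.integer(rowSums(fire))
    docked <- docked & !fire
    if (a < n_ap) {
      u <- stim$ap_times[a + 1] - stim$ap_times[a]
      if (dialect == "continuous-time") {
        lam <- exp(-(k1 + b1) * u)
        p_stay <- p_inf + (1 - p_inf) * lam
        p_fill <- p_inf * (1 - lam)
      } else {
        p_stay <- exp(-b1 * u)          # 1 - B
        p_fill <- 1 - exp(-k1 * u)      # F
      }
      r <- matrix(stats::runif(n_trials * N), n_trials, N)
      docked <- ifelse(docked, r < p_stay, r < p_fill)
    }
  }
  data.frame(
    trial = rep(seq_len(n_trials), times = n_ap),
    ap_index = rep(seq_len(n_ap), each = n_trials),
    quanta_released = as.vector(out)
  )
}
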