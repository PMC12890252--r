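#' Ratiometric indicator calibration
#'
#' Calibration constants of a two-dye ratiometric measurement:
#' limiting ratios at zero and saturating calcium and the indicator
#' dissociation constant.
#'
#' @param r_min Fluorescence ratio at zero calcium.
#' @param r_max Fluorescence ratio at saturating calcium, `> r_min`.
#' @param kd Indicator dissociation constant, uM (2.3 for the
#'   medium-affinity indicator used here).
#' @return Object of class `ratiometry_calib`.
#' @export
ratiometry_calib <- function(r_min, r_max, kd = 2.3) {
  stopifnot(r_min > 0, r_max > r_min, kd > 0)
  structure(list(r_min = r_min, r_max = r_max, kd = kd),
            class = "ratiometry_calib")
}

#' Convert a fluorescence ratio to calcium concentration
#'
#' `[Ca2+] = Kd (R - Rmin) / (Rmax - R)`. Ratios at or above `r_max`
#' are saturated and raise an error; ratios below `r_min` are clipped
#' to zero with a warning.
#'
#' @param r Background-corrected fluorescence ratio (vectorised).
#' @param calib A [ratiometry_calib()].
#' @return [Ca2+] in uM.
#' @export
ratio_to_ca <- function(r, calib) {
  if (any(r >= calib$r_max)) {
    stop("ratio at or above r_max: indicator saturated")
  }
  if (any(r < calib$r_min)) {
    warning("ratio below r_min: negative [Ca2+] clipped to 0")
  }
  pmax(0, calib$kd * (r - calib$r_min) / (calib$r_max - r))
}

#' Inverse of [ratio_to_ca()]
#'
#' @param ca [Ca2+] in uM (vectorised).
#' @param calib A [ratiometry_calib()].
#' @return Fluorescence ratio.
#' @export
ca_to_ratio <- function(ca, calib) {
  stopifnot(all(ca >= 0))
  (calib$kd * calib$r_min + ca * calib$r_max) / (calib$kd + ca)
}

#' Linearized calcium binding ratio of a buffer
#'
#' Incremental binding ratio of a buffer of total concentration
#' `b_total` and dissociation constant `kd` over a calcium excursion
#' from `ca1` to `ca2`:
#' `kappa_B = b_total * kd / ((ca1 + kd) (ca2 + kd))`.
#'
#' @param b_total Total buffer (indicator) concentration, uM.
#' @param kd Buffer dissociation constant, uM.
#' @param ca1 Calcium before the excursion (resting), uM.
#' @param ca2 Calcium after the excursion (transient peak), uM.
#' @return Dimensionless binding ratio.
#' @examples
#' kappa_b(150, 2.3, 0.05, 1.21)
#' @export
kappa_b <- function(b_total, kd, ca1, ca2) {
  stopifnot(b_total >= 0, kd > 0, ca1 >= 0, ca2 >= 0)
  b_total * kd / ((ca1 + kd) * (ca2 + kd))
}

#' Amplitude and decay of a calcium transient
#'
#' Estimates the peak amplitude above baseline and the
#' mono-exponential decay time constant of a single-compartment
#' calcium transient by least squares on the decay phase (from the
#' peak sample onward), with a fitted baseline offset.
#'
#' @param time Time, seconds.
#' @param ca [Ca2+], uM.
#' @return List with `amplitude` (uM above baseline), `tau` (s),
#'   `baseline` (uM), `t_peak` (s).
#' @export
fit_transient <- function(time, ca) {
  stopifnot(length(time) == length(ca), length(ca) >= 5)
  if (stats::sd(ca) < 1e-12) stop("constant trace: no transient to fit")
  ipk <- which.max(ca)
  dec_t <- time[ipk:length(ca)] - time[ipk]
  dec_y <- ca[ipk:length(ca)]
  if (length(dec_y) < 4) stop("too few samples after the peak")
  base0 <- mean(utils::tail(dec_y, max(3, length(dec_y) %/% 10)))
  amp0 <- max(dec_y[1] - base0, 1e-6)
  # tau guess: time to fall to 1/e of the initial excess
  below <- which(dec_y - base0 <= amp0 / exp(1))[1]
  tau0 <- if (is.na(below) || dec_t[below] <= 0) {
    max(dec_t) / 3
  } else dec_t[below]
  df <- data.frame(t = dec_t, y = dec_y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ c0 + a * exp(-t / tau), data = df,
                      start = list(c0 = base0, a = amp0, tau = tau0),
                      lower = c(-Inf, 0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) stop("transient decay fit did not converge")
  cf <- stats::coef(fit)
  if (cf[["tau"]] > 100 * diff(range(time))) {
    warning("decay much slower than the trace: tau poorly constrained")
  }
  list(amplitude = unname(cf["a"]), tau = unname(cf["tau"]),
       baseline = unname(cf["c0"]), t_peak = time[ipk])
}

#' Buffer-free calcium dynamics by extrapolation to zero added buffer
#'
#' The single-compartment model predicts the measured transient
#' amplitude `A` and decay `tau` to depend linearly on the indicator
#' binding ratio `kappa_B`:
#' `1/A = (1 + kappa_S + kappa_B) / DeltaCa_T` and
#' `tau = (1 + kappa_S + kappa_B) / gamma`.
#' Linear fits of `tau` and `1/A` against `kappa_B` therefore give the
#' endogenous binding ratio `kappa_S` from each x-intercept
#' (`-(1 + kappa_S)`), the buffer-free amplitude `a_ca` and decay
#' `tau_ca` from the intercepts at `kappa_B = 0`, the extrusion rate
#' `gamma = (1 + kappa_S) / tau_ca`, and the total calcium increment
#' per AP `delta_ca_total` from the slope of the `1/A` line.
#'
#' The two plots give independent `kappa_S` estimates; both are
#' reported (`kappa_s_tau`, `kappa_s_amp`) rather than averaged.
#'
#' @param kappa_b Indicator binding ratios (>= 2 distinct values).
#' @param tau Measured decay time constants, seconds.
#' @param amplitude Measured transient amplitudes, uM.
#' @return Object of class `buffering_fit`: `kappa_s_tau`,
#'   `kappa_s_amp`, `a_ca` (uM), `tau_ca` (s), `gamma` (1/s),
#'   `delta_ca_total` (uM).
#' @export
extrapolate_buffering <- function(kappa_b, tau, amplitude) {
  stopifnot(length(kappa_b) == length(tau),
            length(kappa_b) == length(amplitude),
            all(tau > 0), all(amplitude > 0))
  if (length(unique(kappa_b)) < 2) {
    stop("need at least two distinct kappa_B values to extrapolate")
  }
  ft <- stats::lm(tau ~ kappa_b)
  fa <- stats::lm(I(1 / amplitude) ~ kappa_b)
  st <- stats::coef(ft)[["kappa_b"]]
  it <- stats::coef(ft)[["(Intercept)"]]
  sa <- stats::coef(fa)[["kappa_b"]]
  ia <- stats::coef(fa)[["(Intercept)"]]
  if (st <= 0 || sa <= 0 || it <= 0 || ia <= 0) {
    stop("degenerate design: buffering lines must have positive ",
         "slope and intercept")
  }
  kappa_s_tau <- it / st - 1
  kappa_s_amp <- ia / sa - 1
  tau_ca <- it
  a_ca <- 1 / ia
  structure(
    list(kappa_s_tau = kappa_s_tau, kappa_s_amp = kappa_s_amp,
         a_ca = a_ca, tau_ca = tau_ca,
         gamma = (1 + kappa_s_tau) / tau_ca,
         delta_ca_total = 1 / sa),
    class = "buffering_fit"
  )
}

#' @export
print.buffering_fit <- function(x, ...) {
  cat("Calcium buffering extrapolation\n")
  cat(sprintf("  kappa_S = %.1f (tau plot) / %.1f (amplitude plot)\n",
              x$kappa_s_tau, x$kappa_s_amp))
  cat(sprintf(
    "  buffer-free: A_Ca = %.3f uM, tau_Ca = %.1f ms, gamma = %.0f /s\n",
    x$a_ca, 1e3 * x$tau_ca, x$gamma))
  cat(sprintf("  total Ca increment per AP: %.1f uM\n", x$delta_ca_total))
  invisible(x)
}

#' Predicted fold-change of release under an external-calcium step
#'
#' Fourth-power dependence of the synaptic response on external
#' calcium with competitive magnesium binding:
#' `f(c) = (c / (1 + c/k_ca + mg/k_mg))^4`; returns
#' `f(ca_hi) / f(ca_lo)`.
#'
#' @param ca_lo,ca_hi External calcium before and after the step, mM.
#' @param k_ca Apparent calcium dissociation constant, mM (default 1.1).
#' @param k_mg Magnesium dissociation constant, mM (default 3.0).
#' @param mg External magnesium, mM (default 1.0).
#' @return Predicted fold-change of the response.
#' @examples
#' ca_cooperativity_ratio(1.3, 2.5)  # about 3.24
#' @export
ca_cooperativity_ratio <- function(ca_lo, ca_hi, k_ca = 1.1, k_mg = 3.0,
                                   mg = 1.0) {
  stopifnot(ca_lo > 0, ca_hi > 0, k_ca > 0, k_mg > 0, mg >= 0)
  f <- function(c) (c / (1 + c / k_ca + mg / k_mg))^4
  f(ca_hi) / f(ca_lo)
}
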