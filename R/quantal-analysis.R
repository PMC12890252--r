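#' MPFA variance-mean parabola
#'
#' Expected ensemble variance of a multiquantal response with mean
#' amplitude `mean_amp` over `n_sites` release sites of quantal size
#' `q` and intra-site quantal coefficient of variation `cv_qs`:
#' `Var = q * I * (1 + cv_qs^2) - I^2 / N` (inter-site quantal
#' variability taken as zero, a single parabola).
#'
#' @param mean_amp Ensemble mean amplitude, pA (vectorised).
#' @param q Quantal size, pA.
#' @param n_sites Number of release sites (positive real).
#' @param cv_qs Intra-site quantal coefficient of variation.
#' @return Variance, pA^2.
#' @examples
#' mpfa_variance(42.4, q = 25, n_sites = 5.3, cv_qs = 0.2)
#' @export
mpfa_variance <- function(mean_amp, q, n_sites, cv_qs = 0.2) {
  stopifnot(q > 0, n_sites > 0, cv_qs >= 0, all(mean_amp >= 0))
  if (any(mean_amp > n_sites * q + 1e-9)) {
    stop("mean_amp exceeds n_sites * q (release probability > 1)")
  }
  q * mean_amp * (1 + cv_qs^2) - mean_amp^2 / n_sites
}

#' Multiple-probability fluctuation analysis (MPFA) fit
#'
#' Least-squares fit of the variance-mean parabola
#' `Var = q I (1 + cv_qs^2) - I^2 / N` to per-pulse (mean, variance)
#' points collected at different release probabilities. The model is
#' linear in `a = q (1 + cv_qs^2)` and `b = 1 / N`, so the fit is an
#' exact linear least-squares solution (optionally weighted).
#'
#' @param points Data frame with columns `mean_amp` (pA) and `var_amp`
#'   (pA^2); at least 3 rows spanning distinct means.
#' @param cv_qs Intra-site quantal CV (default 0.2).
#' @param first_pulse_mean Optional mean amplitude of the first pulse
#'   of the low-frequency train, pA, used to place the resting release
#'   probability `pr_first = first_pulse_mean / (N q)` on the parabola.
#' @param weights Optional nonnegative weights per point.
#' @return Object of class `mpfa_fit`: `n_sites`, `q`, `cv_qs`,
#'   `pr_first` (NA when `first_pulse_mean` is missing).
#' @export
fit_mpfa <- function(points, cv_qs = 0.2, first_pulse_mean = NULL,
                     weights = NULL) {
  stopifnot(all(c("mean_amp", "var_amp") %in% names(points)))
  m <- points$mean_amp
  v <- points$var_amp
  if (length(unique(m)) < 3) {
    stop("need at least 3 points with distinct means")
  }
  fit <- stats::lm(v ~ 0 + m + I(m^2), weights = weights)
  a <- stats::coef(fit)[["m"]]
  b <- -stats::coef(fit)[["I(m^2)"]]
  if (!is.finite(b) || b <= 0) {
    stop("variance-mean relation shows no downward curvature: ",
         "N unidentifiable (points on the rising limb only?)")
  }
  n_sites <- 1 / b
  q <- a / (1 + cv_qs^2)
  if (q <= 0) stop("fitted quantal size is not positive")
  pr_first <- if (is.null(first_pulse_mean)) NA_real_ else {
    first_pulse_mean / (n_sites * q)
  }
  structure(
    list(n_sites = n_sites, q = q, cv_qs = cv_qs, pr_first = pr_first,
         fitted = mpfa_variance(m, q, n_sites, cv_qs), residuals =
           v - mpfa_variance(m, q, n_sites, cv_qs)),
    class = "mpfa_fit"
  )
}

#' @export
print.mpfa_fit <- function(x, ...) {
  cat("MPFA variance-mean fit\n")
  cat(sprintf("  N = %.2f sites, q = %.2f pA (cv_qs = %.2f)\n",
              x$n_sites, x$q, x$cv_qs))
  if (!is.na(x$pr_first)) {
    cat(sprintf("  first-pulse p_r = %.3f\n", x$pr_first))
  }
  invisible(x)
}

#' Quantal size from an asynchronous event-amplitude distribution
#'
#' Fits one- and two-component Gaussian mixtures (maximum likelihood)
#' to an event-amplitude list, selects between them by BIC, and
#' returns the mean and CV of the lowest-mean component — the
#' single-quantum peak of the amplitude histogram.
#'
#' @param event_amps Event amplitudes, pA; at least 50 events.
#' @return List with `q` (pA), `cv`, `n_components`, and the mixture
#'   `model` object.
#' @export
fit_quantal_size <- function(event_amps) {
  event_amps <- as.numeric(event_amps)
  if (length(event_amps) < 50) {
    stop("too few events for a stable mixture fit (need >= 50)")
  }
  # Mclust resolves mclustBIC in the caller's environment; bind it
  # locally so the package need not be attached
  mclustBIC <- mclust::mclustBIC
  model <- mclust::Mclust(event_amps, G = 1:2, modelNames = "V",
                          verbose = FALSE)
  if (is.null(model)) stop("mixture fit failed")
  mu <- model$parameters$mean
  sig <- sqrt(model$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  first <- which.min(mu)
  list(q = unname(mu[first]), cv = unname(sig[first] / mu[first]),
       n_components = model$G, model = model)
}

#' Summaries of a stimulus-train response
#'
#' Computes the paired-pulse ratio (second / first amplitude), the
#' steady-state amplitude (mean of the last five pulses, relative to
#' the first), the synaptic efficacy (steady-state amplitude times
#' stimulation frequency), and — when four or more pulses are given —
#' the facilitation rate constant from [fit_kstf()]. Raw (unnormalized)
#' amplitudes may be given: summaries are invariant to rescaling.
#'
#' @param amps Per-pulse amplitudes (raw or normalized to the first).
#' @param frequency Stimulation frequency, Hz.
#' @return Object of class `train_summary`: `normalized_amps`, `ppr`,
#'   `epsc_ss`, `efficacy`, `k_stf`, `a_ss`, `frequency`.
#' @export
summarize_train <- function(amps, frequency) {
  stopifnot(frequency > 0)
  if (length(amps) < 2) stop("too few pulses (need >= 2 for PPR)")
  if (amps[1] <= 0) stop("first-pulse amplitude must be positive")
  norm <- amps / amps[1]
  ppr <- norm[2]
  if (length(amps) >= 6) {
    epsc_ss <- mean(utils::tail(norm, 5))
    efficacy <- epsc_ss * frequency
  } else {
    warning("fewer than 6 pulses: steady-state summaries unavailable")
    epsc_ss <- NA_real_
    efficacy <- NA_real_
  }
  kfit <- if (length(amps) >= 4) {
    tryCatch(fit_kstf(norm, (seq_along(norm) - 1) / frequency),
             error = function(e) list(k_stf = NA_real_, a_ss = NA_real_))
  } else list(k_stf = NA_real_, a_ss = NA_real_)
  structure(
    list(normalized_amps = norm, ppr = ppr, epsc_ss = epsc_ss,
         efficacy = efficacy, k_stf = kfit$k_stf, a_ss = kfit$a_ss,
         frequency = frequency),
    class = "train_summary"
  )
}

#' @export
print.train_summary <- function(x, ...) {
  cat(sprintf(
    "Train summary (%g Hz): PPR = %.3f, EPSC_ss = %.3f, efficacy = %.2f /s",
    x$frequency, x$ppr, x$epsc_ss, x$efficacy))
  if (!is.na(x$k_stf)) cat(sprintf(", k_STF = %.2f /s", x$k_stf))
  cat("\n")
  invisible(x)
}

#' Rate constant of short-term facilitation
#'
#' Fits the mono-exponential approach
#' `A(t) = a_ss - (a_ss - 1) exp(-k_stf (t - t1))` to a
#' baseline-normalized amplitude sequence, where `a_ss` is the
#' steady-state level and `k_stf` the rate of approach (the same form
#' describes depression, with `a_ss < 1`).
#'
#' @param amps Normalized amplitudes (first element 1 by construction).
#' @param times Pulse times, seconds.
#' @return List with `k_stf` (1/s), `a_ss`, and `flag`
#'   (`"ok"` or `"unidentifiable"`; flat sequences return
#'   `k_stf = NA`, `a_ss = 1`).
#' @export
fit_kstf <- function(amps, times) {
  stopifnot(length(amps) == length(times), length(amps) >= 4,
            all(amps > 0))
  rel <- amps / amps[1]
  if (stats::sd(rel) < 1e-10) {
    return(list(k_stf = NA_real_, a_ss = 1, flag = "unidentifiable"))
  }
  t0 <- times[1]
  a0 <- mean(utils::tail(rel, max(3, length(rel) %/% 4)))
  # crude rate guess from the time to cover half the span
  span <- a0 - 1
  k0 <- if (abs(span) > 0) {
    half <- which(abs(rel - 1) >= abs(span) / 2)[1]
    if (is.na(half) || times[half] <= t0) 1 / diff(range(times)) else
      log(2) / (times[half] - t0)
  } else 1
  df <- data.frame(a = rel, t = times - t0)
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ a_ss - (a_ss - 1) * exp(-k * t), data = df,
                      start = list(a_ss = a0, k = max(k0, 1e-3)),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(k_stf = NA_real_, a_ss = NA_real_, flag = "nonconvergent"))
  }
  cf <- stats::coef(fit)
  list(k_stf = unname(cf["k"]), a_ss = unname(cf["a_ss"]), flag = "ok")
}
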