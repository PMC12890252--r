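#' Observed paired-pulse success/failure pattern
#'
#' Holds the observed first-pulse failure rate and double-failure rate
#' (or a full 4-vector of joint pattern frequencies) for a paired-pulse
#' protocol over `n_sites` binomial release sites.
#'
#' @param p_f1 First-pulse failure rate, in (0, 1\].
#' @param p_f1f2 Double-failure rate, `<= p_f1`. Optional if `joint`
#'   is supplied.
#' @param joint Optional observed 4-vector `(P11, P10, P01, P00)`
#'   summing to 1.
#' @param n_sites Number of release sites N.
#' @param isi Inter-spike interval, seconds.
#' @return An object of class `failure_observation`.
#' @examples
#' failure_observation(p_f1 = 0.106, p_f1f2 = 0.062, n_sites = 6, isi = 0.02)
#' @export
failure_observation <- function(p_f1, p_f1f2 = NULL, joint = NULL,
                                n_sites, isi) {
  stopifnot(p_f1 >= 0, p_f1 <= 1, n_sites >= 1, isi > 0)
  if (!is.null(joint)) {
    stopifnot(length(joint) == 4, all(joint >= 0),
              abs(sum(joint) - 1) < 1e-6)
    joint <- stats::setNames(as.numeric(joint),
                             c("P11", "P10", "P01", "P00"))
    if (is.null(p_f1f2)) p_f1f2 <- joint[["P00"]]
  }
  if (is.null(p_f1f2)) stop("supply p_f1f2 or a full joint 4-vector")
  stopifnot(p_f1f2 >= 0, p_f1f2 <= p_f1)
  structure(
    list(p_f1 = p_f1, p_f1f2 = p_f1f2, joint = joint,
         n_sites = as.integer(n_sites), isi = isi),
    class = "failure_observation"
  )
}

#' Tally a failure observation from per-trial success/failure pairs
#'
#' @param trials Data frame with logical (or 0/1) columns `s1`, `s2`.
#' @param n_sites Number of release sites N.
#' @param isi Inter-spike interval, seconds.
#' @return A [failure_observation()] with the empirical joint.
#' @export
tally_failures <- function(trials, n_sites, isi) {
  stopifnot(all(c("s1", "s2") %in% names(trials)), nrow(trials) >= 1)
  s1 <- as.logical(trials$s1)
  s2 <- as.logical(trials$s2)
  joint <- c(mean(s1 & s2), mean(s1 & !s2), mean(!s1 & s2),
             mean(!s1 & !s2))
  failure_observation(p_f1 = mean(!s1), joint = joint,
                      n_sites = n_sites, isi = isi)
}

#' Per-site release probability from the first-pulse failure rate
#'
#' Inverts `P(F1) = (1 - p_r)^N` for N independent binomial sites.
#'
#' @param p_f1 Observed first-pulse failure rate, in (0, 1\].
#' @param n_sites Number of release sites N.
#' @return Release probability per site, `1 - p_f1^(1/N)`.
#' @examples
#' pr_from_failure(0.106, 6)  # 0.312
#' @export
pr_from_failure <- function(p_f1, n_sites) {
  stopifnot(n_sites >= 1)
  if (any(p_f1 <= 0)) {
    stop("p_f1 must be positive: p_r is unidentifiable from zero failures")
  }
  stopifnot(all(p_f1 <= 1))
  1 - p_f1^(1 / n_sites)
}

# log-space binomial pmf term: C(n, k) a^k (1-a)^(n-k), safe at a in {0,1}
lbin <- function(k, n, a) {
  if (a <= 0) return(ifelse(k == 0, 1, 0))
  if (a >= 1) return(ifelse(k == n, 1, 0))
  exp(lchoose(n, k) + k * log(a) + (n - k) * log1p(-a))
}

# P(n2 docked just before AP2 | n1 docked just after AP1) under the
# one-transition-per-interval scheme: j of the n1 docked sites undock
# (prob B each), i + j of the o1 = N - n1 initially empty sites dock
# (prob F each), with i = n2 - n1.
p_n2_given_n1 <- function(n2, n1, N, B, F_) {
  i <- n2 - n1
  o1 <- N - n1
  j <- 0:n1
  keep <- (i + j >= 0) & (i + j <= o1)
  if (!any(keep)) return(0)
  j <- j[keep]
  sum(lbin(j, n1, B) * lbin(i + j, o1, F_))
}

#' Predict the paired-pulse success/failure joint distribution
#'
#' Exact combinatorial prediction of the four success/failure patterns
#' `(P11, P10, P01, P00)` for two pulses separated by `isi`, over
#' `n_sites` independent release sites with resting occupancy `p_occ`,
#' fusion probability `p_v`, forward docking rate `k1` and undocking
#' rate `b1 = k1 (1 - p_occ) / p_occ`. Between the pulses, docking and
#' undocking follow a Poisson scheme with at most one transition per
#' site: `B = 1 - exp(-b1 isi)`, `F = 1 - exp(-k1 isi)`.
#'
#' The first-pulse failure probability is exactly
#' `(1 - p_v p_occ)^N`; `P01` and `P11` are obtained by subtracting
#' the enumerated `P00` and `P10` from the marginals.
#'
#' @param k1 Forward docking rate, 1/s.
#' @param p_v Vesicular fusion probability.
#' @param n_sites Number of release sites N.
#' @param p_occ Resting site occupancy.
#' @param isi Inter-spike interval, seconds.
#' @return Named numeric vector `(P11, P10, P01, P00)` summing to 1.
#' @examples
#' pr <- pr_from_failure(0.106, 6)
#' predict_joint(5.21, 0.999, 6, pr / 0.999, 0.02)
#' @export
predict_joint <- function(k1, p_v, n_sites, p_occ, isi) {
  N <- as.integer(n_sites)
  stopifnot(p_v >= 0, p_v <= 1, isi > 0, k1 >= 0)
  if (p_occ < 0 || p_occ > 1) {
    stop("inconsistent parameters: p_occ outside [0, 1]")
  }
  b1 <- if (p_occ > 0) k1 * (1 - p_occ) / p_occ else Inf
  B <- 1 - exp(-b1 * isi)
  F_ <- 1 - exp(-k1 * isi)
  P00 <- 0
  P10 <- 0
  for (n0 in 0:N) {
    pn0 <- lbin(n0, N, p_occ)
    if (pn0 == 0) next
    for (n1 in 0:n0) {
      # n0 - n1 vesicles released on pulse 1
      pn1 <- lbin(n0 - n1, n0, p_v)
      if (pn1 == 0) next
      for (n2 in 0:N) {
        p <- pn0 * pn1 * p_n2_given_n1(n2, n1, N, B, F_) *
          (1 - p_v)^n2
        if (n1 == n0) P00 <- P00 + p else P10 <- P10 + p
      }
    }
  }
  pf1 <- (1 - p_v * p_occ)^N
  c(P11 = 1 - pf1 - P10, P10 = P10, P01 = pf1 - P00, P00 = P00)
}

#' Cost of a (k1, p_v) parameter pair against observed failure patterns
#'
#' Sum of squared errors between observed and predicted probabilities
#' over the four success/failure patterns. The per-site release
#' probability is pinned to the observed first-pulse failure rate via
#' [pr_from_failure()], so `p_occ = p_r / p_v`. If the observation
#' carries only `(p_f1, p_f1f2)`, the observed success patterns are
#' split pro rata to the model prediction (their residuals are then
#' zero and the cost reduces to the two failure-pattern terms).
#'
#' @param k1 Forward docking rate, 1/s.
#' @param p_v Vesicular fusion probability.
#' @param obs A [failure_observation()].
#' @return Nonnegative sum of squared errors.
#' @export
failure_cost <- function(k1, p_v, obs) {
  pr <- pr_from_failure(obs$p_f1, obs$n_sites)
  p_occ <- pr / p_v
  if (p_occ > 1) return(Inf)
  pred <- predict_joint(k1, p_v, obs$n_sites, p_occ, obs$isi)
  if (!is.null(obs$joint)) {
    observed <- obs$joint
  } else {
    ps1 <- 1 - obs$p_f1
    pred_s1 <- pred[["P11"]] + pred[["P10"]]
    w11 <- if (pred_s1 > 0) pred[["P11"]] / pred_s1 else 0.5
    observed <- c(P11 = ps1 * w11, P10 = ps1 * (1 - w11),
                  P01 = obs$p_f1 - obs$p_f1f2, P00 = obs$p_f1f2)
  }
  sum((observed - pred)^2)
}

#' Fit the refilling rate and fusion probability to failure patterns
#'
#' Bounded minimisation of [failure_cost()] over `(k1, p_v)` using a
#' deterministic multi-start grid (default 5 x 5 over the box) followed
#' by L-BFGS-B local search from each start. The default box `[4, 8] x
#' [0.8, 1]` reflects the physiological range of the baseline docking
#' rate and near-unity fusion probability at these synapses.
#'
#' @param obs A [failure_observation()].
#' @param bounds Numeric vector `(k1_lo, k1_hi, pv_lo, pv_hi)`.
#' @param n_starts Grid points per dimension for the multi-start.
#' @return Object of class `failure_fit`: list with `k1`, `p_v`,
#'   derived `p_r`, `p_occ`, `b1`, the `predicted_joint`, the `cost`,
#'   and flags `converged`, `on_boundary`.
#' @export
fit_failure_model <- function(obs, bounds = c(4, 8, 0.8, 1),
                              n_starts = 5) {
  stopifnot(length(bounds) == 4, bounds[1] <= bounds[2],
            bounds[3] <= bounds[4])
  lower <- c(bounds[1], bounds[3])
  upper <- c(bounds[2], bounds[4])
  f <- function(par) failure_cost(par[1], par[2], obs)
  starts <- expand.grid(
    k1 = seq(lower[1], upper[1], length.out = n_starts),
    p_v = seq(lower[2], upper[2], length.out = n_starts)
  )
  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), f, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimisation failed from every start")
  if (!any_converged) {
    warning("optimiser did not report convergence; best iterate returned")
  }
  k1 <- best$par[1]
  p_v <- best$par[2]
  tol <- 1e-8 * pmax(1, upper - lower)
  on_boundary <- any(abs(best$par - lower) < tol |
                       abs(best$par - upper) < tol)
  pr <- pr_from_failure(obs$p_f1, obs$n_sites)
  p_occ <- pr / p_v
  structure(
    list(k1 = k1, p_v = p_v, p_r = pr, p_occ = p_occ,
         b1 = k1 * (1 - p_occ) / p_occ,
         predicted_joint = predict_joint(k1, p_v, obs$n_sites, p_occ,
                                         obs$isi),
         cost = best$value, converged = any_converged,
         on_boundary = on_boundary, bounds = bounds, obs = obs),
    class = "failure_fit"
  )
}

#' @export
print.failure_fit <- function(x, ...) {
  cat("Binomial-site failure-pattern fit\n")
  cat(sprintf("  k1 = %.3f /s, p_v = %.4f (cost %.3g%s)\n", x$k1, x$p_v,
              x$cost, if (x$on_boundary) ", on boundary" else ""))
  cat(sprintf("  derived: p_r = %.3f, p_occ = %.3f, b1 = %.2f /s\n",
              x$p_r, x$p_occ, x$b1))
  cat("  predicted joint (%):",
      paste(sprintf("%s=%.2f", names(x$predicted_joint),
                    100 * x$predicted_joint), collapse = ", "), "\n")
  invisible(x)
}
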