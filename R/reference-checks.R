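#' Recompute the study's printed derived quantities
#'
#' Evaluates, from the printed inputs alone, the derived quantities the
#' study reports for the baseline characterisation of these synapses:
#' the per-site release probability inverted from the first-pulse
#' failure rate (10.6%, N = 6), the docking/undocking rate
#' decomposition of the occupancy relaxation rate (23/s at resting
#' occupancy 0.3), the four predicted paired-pulse success/failure
#' pattern probabilities at the fitted optimum (k1 = 5.21/s,
#' p_v = 0.999, ISI 20 ms), and the fourth-power prediction for the
#' external-calcium step from 1.3 to 2.5 mM.
#'
#' @return Data frame with columns `check`, `computed`, `printed`,
#'   `units`.
#' @export
reference_checks <- function() {
  pr <- pr_from_failure(0.106, 6)
  rates <- decompose_rates(0.3, 23)
  joint <- predict_joint(k1 = 5.21, p_v = 0.999, n_sites = 6,
                         p_occ = pr / 0.999, isi = 0.02)
  data.frame(
    check = c("release probability from failure rate",
              "baseline docking rate k1",
              "baseline undocking rate b1",
              "resting occupancy k1/(k1+b1)",
              "predicted P11", "predicted P10",
              "predicted P01", "predicted P00",
              "external-Ca fold increase (1.3 to 2.5 mM)"),
    computed = c(pr, rates$k1, rates$b1,
                 steady_state_occupancy(rates$k1, rates$b1),
                 100 * joint[["P11"]], 100 * joint[["P10"]],
                 100 * joint[["P01"]], 100 * joint[["P00"]],
                 ca_cooperativity_ratio(1.3, 2.5)),
    printed = c(0.312, 6.9, 16.1, 0.3, 41.5, 47.9, 4.93, 5.67, 3.24),
    units = c("", "1/s", "1/s", "", "%", "%", "%", "%", "fold"),
    stringsAsFactors = FALSE
  )
}
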