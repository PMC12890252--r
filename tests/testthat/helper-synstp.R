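# Shared fixtures: the baseline kinetic regime of these synapses
baseline_pool <- function(p_v = 1) {
  pool_params(n_sites = 6, k1_base = 6.9, b1 = 16.1, p_v = p_v)
}

# pool with a prescribed resting occupancy (b1 derived from k1)
pool_at_occupancy <- function(n_sites, k1, p_occ, p_v) {
  pool_params(n_sites, k1, k1 * (1 - p_occ) / p_occ, p_v)
}

# the printed paired-pulse observation: P(F1) = 10.6%, P(F1,F2) = 6.2%
printed_failure_obs <- function() {
  failure_observation(p_f1 = 0.106, p_f1f2 = 0.062, n_sites = 6,
                      isi = 0.02)
}

# independent per-site oracle for the two-pulse joint distribution:
# under the one-transition-per-interval scheme all sites are i.i.d., so
# pattern probabilities factorise across sites. Enumerates the per-site
# paths (initial docking, release at AP1, interval transition, release
# at AP2) directly -- no shared code with predict_joint().
site_factor_joint <- function(k1, p_v, n_sites, p_occ, isi) {
  b1 <- k1 * (1 - p_occ) / p_occ
  B <- 1 - exp(-b1 * isi)
  F_ <- 1 - exp(-k1 * isi)
  p_norel_both <- 0   # site silent on both pulses
  p_norel_2 <- 0      # site silent on pulse 2 (any pulse-1 outcome)
  for (d0 in c(TRUE, FALSE)) {
    pd0 <- if (d0) p_occ else 1 - p_occ
    rel1_opts <- if (d0) c(TRUE, FALSE) else FALSE
    for (rel1 in rel1_opts) {
      prel1 <- if (!d0) 1 else if (rel1) p_v else 1 - p_v
      d_mid <- d0 && !rel1
      for (d2 in c(TRUE, FALSE)) {
        pd2 <- if (d_mid) {
          if (d2) 1 - B else B
        } else {
          if (d2) F_ else 1 - F_
        }
        p_norel2_here <- if (d2) 1 - p_v else 1
        w <- pd0 * prel1 * pd2 * p_norel2_here
        p_norel_2 <- p_norel_2 + w
        if (!rel1) p_norel_both <- p_norel_both + w
      }
    }
  }
  P00 <- p_norel_both^n_sites
  PF2 <- p_norel_2^n_sites
  PF1 <- (1 - p_v * p_occ)^n_sites
  c(P11 = 1 - PF1 - (PF2 - P00), P10 = PF2 - P00,
    P01 = PF1 - P00, P00 = P00)
}
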