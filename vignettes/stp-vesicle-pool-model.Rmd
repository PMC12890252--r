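---
title: "Vesicle-pool kinetics, failure analysis and calcium buffering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vesicle-pool kinetics, failure analysis and calcium buffering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstp)
```

# The problem

Small cortical synapses with a handful of release sites can show the
unusual combination of a near-unity vesicular fusion probability
(`p_v`) with low resting site occupancy (`p_occ`). Under that regime,
short-term facilitation during a train is not caused by an increase in
`p_v` but by progressive *overfilling* of release sites: a
calcium-sensing protein (synaptotagmin-7) accelerates the refilling of
emptied sites. This package implements the quantitative machinery
needed to test that picture: a one-step pool model, a sequential
calcium-binding scheme driving the refilling rate, exact binomial
statistics of paired-pulse failures, variance–mean (MPFA) quantal
analysis, and the calcium-binding-ratio algebra used to infer
buffer-free calcium dynamics from ratiometric imaging.

# The refilling model

A connection has `N` independent release sites. Each site is empty or
holds one fusion-competent vesicle; docking occurs at rate `k1` (per
second) and undocking at `b1`. The expected occupancy `rho` obeys

    d rho/dt = k1 (1 - rho) - b1 rho - p_v rho delta(t - t_AP)

so at rest `rho = k1/(k1 + b1)` and perturbations relax at `k1 + b1`.
Release is an instantaneous multiplicative event (`rho -> (1 - p_v)
rho` at each AP), never a rate spread over a time step, which keeps
per-pulse amplitudes independent of the integration step. The default
regime used throughout the examples is `N = 6`, `k1 = 6.9`/s,
`b1 = 16.1`/s (resting occupancy 0.3, relaxation 23/s) and `p_v = 1`.

`integrate_deterministic()` uses forward Euler (default step 1 ms,
configurable; arbitrary nonuniform grids are accepted). Forward Euler
is first-order: at the 23/s relaxation rate the global error on the
occupancy is bounded by `0.3 * 23 * h / (2e)`, about `1.3e-5` at
`h = 1e-5` s, and the tests verify both this bound and the first-order
step-halving behaviour. At the default 1 ms step, halving the step
moves per-pulse amplitudes by less than 0.5%.

`simulate_stochastic()` simulates each site explicitly, in two
dialects. The *continuous-time* dialect uses the exact two-state
Markov propagator between APs and is the physically faithful oracle
for the deterministic model. The *per-interval* dialect allows at most
one transition per site per inter-AP interval (undock with
`B = 1 - exp(-b1 dt)`, dock with `F = 1 - exp(-k1 dt)`, vacated sites
do not refill within the interval); this is exactly the scheme the
combinatorial failure analysis assumes, so it — and not the
continuous-time dialect — is the Monte-Carlo oracle for
`predict_joint()`. The two dialects differ at order `(k1 dt)(b1 dt)`,
negligible at a 20 ms interval for the rates above but kept distinct
on principle.

# The calcium/Syt7 drive

The sensor sees, per AP, a brief local transient modelled as a
Gaussian in time (peak 40 µM, centre 0.25 ms after the AP, sigma
0.085 ms, i.e. 0.2 ms FWHM) plus a residual component (1 µM amplitude,
50 ms decay), superposed linearly across APs with no saturation. The
Gaussian is *peak-scaled*: a density-normalised Gaussian has units of
1/time, so fixing the physical peak at 40 µM is the dimensionally
consistent reading, and the waveform builder implements that.

Binding is a sequential chain `S_0 ... S_n`: forward rate
`(n - j) k_on [Ca]`, backward rate `(j + 1) k_off b^j` with
`k_on = 7`/µM/s, `k_off = 10`/s and cooperativity factor `b = 0.35`
applied geometrically to successive *unbinding* steps (the allosteric
sensor convention — successive ions bind ever more tightly). Scaling
forward rates instead is the main alternative convention; the chain
is parameterised so that choice is localised in one place
(`chain_rates`). The number of ions is set to `n = 5` by default
(two to three ions on each of two C2 domains), configurable 2–6. With
`b = 1` the chain's equilibrium is exactly binomial in
`[Ca]/([Ca] + k_off/k_on)`, which the tests verify against the
integrator.

The fully bound fraction gates refilling:
`k1(t) = k1_base + K1_max * S_n(t)` with `K1_max = 300`/s. In
knockdown mode `k1` is frozen at baseline.

Integration uses a two-timescale grid: 5 µs steps within a 2 ms
window after each AP (resolving the 85 µs Gaussian), 1 ms elsewhere;
the binding chain and the pool share the grid. The tests check the
composite against a uniform 1 µs grid (per-pulse amplitudes within
1%). The master-equation update is written as antisymmetric fluxes,
so probability is conserved to machine precision regardless of step.

With these defaults the model reproduces the characteristic
behaviour: at 40 Hz a strong paired-pulse depression (`PPR ~ 0.44`)
followed by delayed facilitation above baseline, pure depression in
knockdown mode, and a facilitation rate constant `k_STF` that grows
monotonically with stimulation frequency (about 1.3/s at 5 Hz). The
late-train amplitudes run above the experimentally observed ~2-fold
facilitation — the model has no site-clearance or endocytic
limitation, and that overshoot is a known limitation, most visible at
high frequency.

The initial condition for train simulations is steady-state occupancy
with the chain fully unbound; resting calcium defaults to zero in the
drive (the measured 50 nM resting level contributes negligibly to
occupancy of a sensor whose first binding step has `K_D ~ 1.4` µM,
and including it would pre-load the chain only at the fourth decimal).

# Paired-pulse failure analysis

For two pulses `isi` apart, `predict_joint()` enumerates
`P(n0) P(n1|n0) P(n2|n1)` over initial docked count, post-release
count and pre-second-pulse count, with binomial occupancy, binomial
release and the one-transition-per-interval docking/undocking kernel,
then folds in the second-pulse failure factor `(1 - p_v)^{n2}`. The
first-pulse failure marginal is exactly `(1 - p_v p_occ)^N`.
Binomial terms are computed in log space (`lchoose`), giving headroom
to `N = 20`. Two independent oracles guard the implementation: a
per-site path enumeration (patterns factorise across i.i.d. sites)
and the per-interval Monte-Carlo dialect.

`fit_failure_model()` minimises the sum of squared errors over the
four patterns with `p_r` pinned to the observed first-pulse failure
rate, using a deterministic 5×5 multi-start grid with L-BFGS-B within
the box (default `[4, 8] × [0.8, 1]`); no randomness, so results are
exactly reproducible. When only `(P(F1), P(F1,F2))` are available the
observed success patterns are split pro rata to the model prediction,
which zeroes their residuals. An important consequence, demonstrated
in `analysis/02_failure_analysis.R`: with failure rates alone the
cost is nearly flat along a curve in `(k1, p_v)` and its minimum sits
at the `k1` lower bound — the published point estimate for this kind
of data is only pinned down by the full observed success/failure
split. The forward predictions at that published optimum are
reproduced to print precision either way.

# Quantal analysis

`mpfa_variance()` is the single-parabola MPFA relation
`Var = q I (1 + CV_qs^2) - I^2 / N` with intra-site quantal CV fixed
(0.2 by default) and inter-site variability set to zero. The relation
is linear in `(q (1 + CV^2), 1/N)`, so `fit_mpfa()` solves the exact
(optionally weighted) linear least-squares problem rather than
iterating; a non-negative curvature is reported as "N unidentifiable"
(points confined to the rising limb). Quantal size from asynchronous
event lists (`fit_quantal_size()`) fits 1- and 2-component Gaussian
mixtures by maximum likelihood and picks by BIC, reporting the
lowest-mean component — the single-quantum peak — requiring at least
50 events. Train summaries define PPR as the second normalized
amplitude, the steady state as the mean of the last five pulses, and
efficacy as steady state × frequency; `fit_kstf()` fits
`A(t) = a_ss - (a_ss - 1) exp(-k_STF (t - t1))`, flagging flat
sequences as unidentifiable rather than guessing.

# Calcium buffering

Ratios convert through `[Ca] = Kd (R - Rmin)/(Rmax - R)` (saturated
ratios are an error, sub-`Rmin` ratios clip to zero with a warning).
The incremental indicator binding ratio uses the resting and peak
calcium of each condition. The single-compartment model makes both
`tau` and `1/A` linear in `kappa_B`; `extrapolate_buffering()` fits
both lines and reports *both* x-intercept estimates of `kappa_S`
(`kappa_s_tau`, `kappa_s_amp`) without averaging, since with real
data they differ and the discrepancy is informative. Derived
quantities satisfy `delta_ca_total = a_ca (1 + kappa_s_amp)` and
`gamma tau_ca = 1 + kappa_s_tau` identically by construction. Time is
seconds internally; printed reports use ms for decay constants.

# Synthetic data: what it does and does not emulate

The generators provide every data shape the analyses consume, with a
ground-truth sidecar and full determinism from a single seed. Quantal
amplitudes are Gaussian truncated at zero (exact inverse-CDF draws);
at `CV <= 0.3` the truncation bias is below 0.04% of `q` and is
ignored. The line-scan generator computes the indicator binding ratio
self-consistently (the peak depends on the load and vice versa; a
fixed-point iteration converges in a few steps) and aligns one scan
line with the stimulus so the first decay sample sits at the
transient onset. Detection thresholding of paired trials uses `q/2`
by default; with nonzero quantal variability a small fraction of
single-quantum responses falls below any threshold, which is a
property of thresholded detection itself — the oracle-closure tests
therefore use `CV_qs = 0`.

What passing these tests shows: the estimators invert their own
generative models at realistic parameter values and sample sizes.
What it does not show: robustness to features of real recordings the
generators omit — amplitude rundown, AP failures, electrode drift,
correlated noise, asynchronous-release contamination of phasic
amplitudes, and dye bleaching.

# Problem sizes and tolerances

The test suite runs stochastic closures at 10^5 trials (3-standard-
error criteria), the Monte-Carlo validation of the failure prediction
at 10^6 trials, MPFA recovery at 100 trials per probability point
(15% tolerance) and 10^4 trials (5%), and buffering recovery
noise-free (exact), with 5% channel noise, and with 10% noise at 20
sweeps (25%). These sizes make the full suite run in well under a
minute while leaving Monte-Carlo error comfortably below each
tolerance.

# Known limitations

* One-step refilling only: no explicit two-pool (loose/tight docking)
  states, no site clearance, no endocytosis — hence the late-train
  overshoot at high frequency.
* No spatial calcium: the waveform is a prescribed time course, with
  linear superposition and no channel facilitation/inactivation.
* The cooperativity convention and the number of binding steps are
  choices among textually equivalent alternatives (see above); both
  are parameterised and testable rather than hard-coded.
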