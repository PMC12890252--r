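Package: synstp
Title: Vesicle-Pool Kinetics, Quantal Analysis and Calcium Buffering at
    Facilitating Cortical Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for short-term plasticity at
    recurrent cortical synapses with a small number of release sites.
    Implements a one-step vesicle-pool refilling model (deterministic
    Euler integration and stochastic per-site simulation), a sequential
    allosteric calcium-binding scheme for synaptotagmin-7 that drives a
    time-dependent docking rate, exact binomial-site analysis of
    paired-pulse success/failure patterns with bounded optimisation of
    the docking rate and vesicular fusion probability,
    multiple-probability fluctuation analysis (MPFA) of variance-mean
    data, quantal-size estimation from asynchronous event amplitudes,
    train summaries (paired-pulse ratio, steady-state amplitude,
    synaptic efficacy, facilitation rate), and ratiometric
    calcium-imaging algebra (indicator calibration, calcium binding
    ratios, buffer-free transient extrapolation). Seeded synthetic-data
    generators with known ground truth cover every data shape the
    analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
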