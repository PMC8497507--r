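Package: ubcontinuum
Title: Temporal-Response Continuum of Cerebellar Unipolar Brush Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of the unipolar brush cell (UBC)
    temporal-response continuum. Generates synthetic UBC populations with
    log-uniformly distributed response peak times, biphasic metabotropic
    synaptic currents (mGluR1 inward, mGluR2/3 outward, fast ionotropic),
    a supra-linear f-I transform and inhomogeneous Poisson spike trains;
    estimates instantaneous firing rates from spike trains; fits
    log-Gaussian temporal response profiles and extracts per-cell features
    (peak time, half-width, half-decay, pause, response class); assembles
    population-level statistics (sorted heatmaps, rank regressions,
    inverted soft-plus amplitude law, log-uniformity tests, and the
    1/sqrt(N)-normalized population-amplitude shifted power law); and
    implements latent-gradient transcriptomic ordering via non-negative
    matrix factorization of log counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
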