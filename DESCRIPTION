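Package: crcoupling
Title: Cardiorespiratory Coupling Analysis for Infant and Adult Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cardiorespiratory coupling from R-peak,
    RR-interval, respiration and single-lead ECG recordings across a
    pre/stimulus/post protocol. Implements smoothness-priors detrending and
    4 Hz resampling of RR series, age-specific Welch spectral metrics (HF,
    LF/HF), orthogonal subspace projection of the RR series onto a delayed
    respiration subspace with the relative respiratory power statistic (Px),
    mean phase coherence, bivariate phase-rectified signal averaging with
    cross-correlation and kernel-density mutual-information coupling
    strengths, magnitude-squared coherence, ECG-derived respiration by the
    slope-range method, nonparametric repeated-measures group statistics
    with a coupling-directionality test, and a synthetic cardiorespiratory
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    Matrix,
    nortest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
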