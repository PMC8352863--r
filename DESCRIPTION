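Package: mobersp
Title: Sensorimotor Alpha/Beta Desynchronization Analysis for Dual-Task Mobile EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An independent-component (IC) level analysis pipeline for
    button-press-related sensorimotor desynchronization during sitting and
    walking in younger and older adults. Provides Morlet-wavelet
    event-related spectral perturbation (ERSP) computation with trial
    time-warping and single-trial normalization, Welch power spectral
    density estimation with aperiodic (1/f) spectral parameterization,
    repetitive ROI-targeted k-means clustering of equivalent-dipole ICs
    with weighted solution scoring, data-driven extraction of alpha and
    beta suppression measures, proportional dual-task costs, and the
    group-level statistics layer (mixed 2x2 ANOVA with generalized eta
    squared, Welch t-tests, ordered quantile normalization, partial
    Spearman correlations, FDR adjustment). A synthetic cohort generator
    with planted ground-truth effects stands in for raw EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
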