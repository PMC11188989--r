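Package: megspeech
Title: Sensor-Space MEG Analysis of Covert and Overt Speech Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two participant cohorts from epoched
    magnetoencephalography (MEG) recordings collected during covert
    (imagined) and overt speech tasks.  The package provides a portable
    epoch container, zero-phase Butterworth/notch signal conditioning,
    canonical-band power estimation (Welch), pairwise sensor Pearson
    correlation summaries, amplitude-envelope-correlation (AEC)
    functional connectivity, cohort band-power distance heatmaps with
    one-way ANOVA and Tukey post-hoc comparison, and single-trial
    cohort classification with regularized linear discriminant analysis
    under leave-one-participant-pair-out cross-validation.  A synthetic
    two-cohort oscillatory data generator with a shared-source coupling
    model makes the full pipeline testable end to end without access to
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
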