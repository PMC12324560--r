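Package: bbpredict
Title: Brain-Behavior Prediction from Regional, Connectivity and Graph
    Signal Processing fMRI Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compare resting-state fMRI feature families for predicting
    behavioral targets. Implements nine feature extractors from parcellated
    BOLD time series: regional mean, standard deviation, mean squared
    successive difference (BOLD variability), fractional amplitude of
    low-frequency fluctuations (fALFF), Pearson functional connectivity, and
    four graph-signal-processing features built on structural-connectome
    harmonics (graph power spectral density, structural decoupling index,
    coupled and decoupled functional connectivity). Prediction uses
    family-grouped train/test splits with nested cross-validation
    (elastic net, kernel ridge regression, support vector machine) and
    permutation-based significance, plus scaling experiments over training-set
    size and scan time. A synthetic cohort generator with controllable
    graph-spectral energy and feature-linked effect sizes makes the whole
    pipeline testable without access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
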