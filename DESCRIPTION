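Package: thermofit
Title: Feedback-Control Modelling of Finger Skin Temperature Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the recovery of finger cutaneous temperature after an
    isometric handgrip exercise as a homeostatic negative-feedback control
    system with four functional parameters: the lag time before active
    re-warming starts, the open-loop plant pole, a constant environmental
    disturbance input, and an integral controller gain. Provides exact
    simulation of the switched open-loop/closed-loop response, a three-stage
    parameter estimation pipeline (graphical initialisation, Nelder-Mead
    refinement, bounded nonlinear least squares) for per-region thermal
    time series, a synthetic cohort generator with group-specific parameter
    populations, and the downstream group-comparison and region-classification
    statistics (rank-sum tests, logistic regression, ROC cutoff selection,
    confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
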