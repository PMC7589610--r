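Package: firefit
Title: Partial Least-Squares Prediction of Occupational Fitness Task Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A from-scratch partial least-squares regression (PLSR) pipeline
    for predicting occupational ability-task completion times from physical
    fitness measurements. Implements NIPALS-style component extraction with
    block deflation, leave-one-out PRESS/Q-squared cross-validation for
    choosing the number of latent components, one-at-a-time perturbation
    sensitivity analysis over an eight-level predictor grid, train/test
    evaluation with relative-error accuracy metrics, and a seeded synthetic
    data generator emulating a small firefighter cohort with a low-rank
    latent predictor-response structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
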