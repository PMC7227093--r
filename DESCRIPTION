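Package: centersim
Title: Single-Center Versus Multi-Center Designs for Prognostic
    Signature Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Daniel", "Keller", email = "dkeller@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo simulation framework for comparing single-center
    (SC) and multi-center (MC) gene-expression cohorts as discovery and
    validation sets for molecular prognostic models.  Cohorts are generated
    from a latent-state batch-effect model (gene-wise basal levels, a graded
    linear signal driven by a continuous true state, center-specific additive
    shifts, latent-factor correlation patterns and noise rescaling), processed
    with per-sample standardization and parametric empirical-Bayes batch
    correction, and used to fit lasso signatures with cross-validated penalty
    selection by the one-standard-error rule.  Four performance scores are
    computed for every discovery x validation design combination: false
    discovery rate of the selected gene set, mean squared prediction error on
    uncorrected validation data, chance of successful validation, and
    calibration slope.  Includes the three parameter-sweep scenarios (signal
    strength, number of informative genes, sample size) and an experiment
    quantifying the quality of the MSPE estimator under SC and MC validation.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    graphics,
    grDevices,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
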