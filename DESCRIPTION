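Package: ettmachine
Title: Targeted Machine Learning for Center-Level Effects Among the Treated
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effect of a binary center-level exposure (for
    example treatment at a large- versus small-volume trauma center) on
    patient outcomes among the treated (ETT), from observational
    patient-level cohorts with missing covariates.  Provides a
    missingness-indicator design basis, a from-scratch cross-validated
    ensemble stacker (super learner), four estimators of the ETT
    (unadjusted difference, outcome-regression substitution, targeted
    maximum likelihood with an iterative dual fluctuation, and
    propensity-score caliper matching with replacement), nonparametric
    bootstrap and influence-curve inference, counterfactual-residual
    diagnostics, and a synthetic trauma-cohort generator with known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pheatmap
Config/testthat/edition: 3
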