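Package: breathlasso
Title: Adaptive LASSO Discriminant Models for Breath Volatile Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating penalized logistic
    discriminant models of volatile-compound concentrations in alveolar
    (end-expiratory) breath. Provides quality-control filters for
    alveolar-origin verification (CO2 threshold) and environmental
    contamination (paired t-test against room air), a weighted-L1
    (adaptive LASSO) logistic regression solver with cross-validated
    penalty selection implemented by cyclic coordinate descent, the
    iterated three-stage selection pipeline (screening LASSO, weight
    generation, adaptive LASSO) with bootstrap percentile confidence
    intervals, ROC analysis with DeLong variance and paired ROC-area
    comparison, and a log-normal synthetic cohort generator
    parameterized from published group summary statistics so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
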