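Package: axsurv
Title: Axillary Surgery Extent and Breast-Cancer-Specific Survival in
    Registry-Like Cohorts
Version: 0.1.0
Authors@R:
    person("Axsurv", "Maintainers", email = "maintainers@axsurv.org",
           role = c("aut", "cre"))
Description: Tools to study the association between the extent of axillary
    surgery (sentinel lymph node biopsy versus axillary lymph node
    dissection) and breast-cancer-specific survival in registry-style
    cohorts where the surgical procedure is not recorded directly.
    Provides a synthetic cohort generator with known ground truth, a
    two-step procedure-inference classifier (deterministic node-count
    rules followed by a Bayesian logistic regression with informative
    priors), multiple imputation by chained equations with predictive
    mean matching, propensity-score nearest-neighbour caliper matching
    with covariate-balance diagnostics, Kaplan-Meier / log-rank /
    Cox proportional-hazards analyses with matched-pair cluster-robust
    variance, and positive-to-removed lymph-node-ratio prognostic models
    for high nodal burden, orchestrated by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
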