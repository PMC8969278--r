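Package: gaitmat
Title: Gait Feature Extraction and Classification from Raw Instrumented-Walkway Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs individual footfalls from raw pressure-sensor point
    clouds recorded by an instrumented walkway, extracts standard spatiotemporal
    gait parameters together with geometric features (convex-hull footprint
    area, base-of-support area, line-of-progression deviation, toe direction),
    and classifies walks as patient or control through a leakage-aware pipeline:
    SMOTE class balancing, train-fitted z-scaling, height normalisation,
    Pearson correlation filtering, ANOVA-F feature ranking with cross-validated
    subset-size selection, and grouped k-fold evaluation of logistic-regression,
    support-vector-machine and gradient-boosted-tree classifiers. A parametric
    walkway simulator with per-footfall ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    xgboost,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
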