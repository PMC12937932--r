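Package: kinectome
Title: Subject-Specific Kinematic Similarity Networks for Gait Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-specific body-segment similarity networks from
    multi-segment gait recordings using kernel density estimates and the
    Jensen-Shannon divergence, extracts threshold-averaged graph-theoretical
    and kinematic dispersion features, classifies disease status with a
    voting-feature-selection plus gradient-boosted-tree pipeline under nested
    cross-validation, and identifies stable explanatory features via Shapley
    cumulative-importance and cross-fold stability analysis. Includes a
    synthetic cohort generator with controllable Parkinsonian-like effects,
    univariate group statistics with false-discovery-rate control, clinical
    correlation screening, and sensitivity power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
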