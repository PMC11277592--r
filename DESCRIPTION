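Package: resieve
Title: Repeated Sieving for Variable Selection and Prediction with
    High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparse prediction models from high-dimensional data
    (features far outnumbering subjects) by repeated sieving: features are
    partitioned into small blocks, unpenalized forward stepwise regression
    with significance thresholds for insertion and deletion is run within
    each block, the procedure is repeated over random permutations of the
    feature order, and a final stepwise fit on the pooled candidates yields
    the prediction model. Supports binary outcomes (logistic regression)
    and right-censored time-to-event outcomes (Cox proportional hazards
    with Efron tie handling). Includes risk-score evaluation (ROC/AUC,
    Harrell's concordance index, univariate Cox significance), a
    block-correlated Gaussian simulation engine with calibrated uniform
    censoring, and a benchmarking harness against L1 (lasso) and L1+L2
    (elastic net) penalized comparators fitted by cross-validated
    coordinate descent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
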