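Package: repsel
Title: Ensemble Feature Selection with Permutation-Assisted Group Lasso for
    Immune Repertoire VJ Gene Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ensemble feature selection for high-dimensional binary
    classification problems with small sample sizes, motivated by adaptive
    immune receptor repertoire (AIRR) sequencing studies.  Outputs of several
    base feature selectors (information gain, correlation-based feature
    selection, SVM-RFE, Boruta-style shadow-feature screening, cross-validated
    permutation importance, and the lasso) are aggregated into a best-rank
    candidate set, expanded by correlation, partitioned into correlation
    blocks, and screened with a group-lasso logistic model whose penalty level
    is tuned against row-permuted pseudo-variables.  Includes a front-end that
    derives VJ-gene-usage feature matrices from AIRR rearrangement tables, a
    simulation engine with correlated causal groups and a logistic outcome,
    and a benchmark harness with selection-quality, stability, and prediction
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    ranger,
    xgboost,
    class,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
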