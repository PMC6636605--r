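Package: dnecpm
Title: Dynamic Nodal-Efficiency Connectome Predictive Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts continuous clinical outcomes (UPDRS-III motor scores)
    from resting-state fMRI ROI time series via dynamic nodal-efficiency
    (dnE) correlation networks and L1-penalized (LASSO) connectome
    predictive modeling under leave-one-out cross-validation. Provides
    temporal signal conditioning (volume discarding, Friston-24 nuisance
    regression, zero-phase band-pass filtering, framewise-displacement
    based subject exclusion), sliding-window graph construction with
    weighted nodal global efficiency, inter-node correlation of efficiency
    curves, permutation inference, macro-region aggregation of regression
    weights, and a synthetic-cohort generator with planted ground truth
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
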