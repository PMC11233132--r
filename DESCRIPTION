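Package: cbrecruit
Title: Selective Recruitment Analysis for Cortico-Cerebellar Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether cerebellar fMRI activity exceeds the
    prediction of a task-invariant cortico-cerebellar connectivity model
    (selective recruitment). Provides regularized multivariate regression
    (ridge and lasso) for estimating parcel-to-voxel connectivity weights
    with cross-validated hyperparameter tuning, transfer prediction of
    cerebellar region-of-interest activity for new subjects and conditions,
    per-subject rescaling of predictions anchored at the resting baseline,
    signed-residual gating statistics with repeated-measures ANOVA and
    paired post-hoc tests, and a synthetic-data generator with known
    connectivity and injectable input gating for parameter-recovery,
    type-I-error calibration, and power experiments.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
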