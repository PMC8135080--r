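Package: plateletpanel
Title: Platelet Proteomic Biomarker Panel Discovery for Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Platelet", "Panel Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering blood-platelet protein biomarker
    panels of cognitive decline from labeled TMT (tandem mass tag) abundance
    matrices. Covers Perseus-style preprocessing (median normalization,
    downshifted-normal imputation), per-protein Student t differential testing
    across Ctrl/MCI/AD contrasts, k-means trajectory clustering over disease
    stages, Pearson correlation of every protein with the MMSE cognitive score,
    hypergeometric over-representation analysis against GMT gene sets, NIPALS
    PLS-DA with variable-importance-in-projection (VIP) candidate triage, and
    exhaustive leave-one-out evaluation of candidate panels with a
    class-balanced ridge logistic classifier (ROC/PR/confusion metrics). A
    synthetic-cohort generator with planted ground truth makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
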