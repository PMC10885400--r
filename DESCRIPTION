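Package: vterisk
Title: Risk-Stratified Scoring for Venous Thromboembolism After
    Minimally Invasive Prostatectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates an additive integer risk score for
    90-day venous thromboembolism (VTE) after minimally invasive radical
    prostatectomy. Provides a synthetic cohort generator with calibrated
    rare-event prevalence, a boosted-regression-tree (BRT) stage exposing
    relative influence and partial dependence, importance-banding into
    score points with threshold selection from partial-dependence curves,
    a simulation-based cut-point estimator with an exact enumeration
    oracle and a minimum-positive calibration rule, Youden and bootstrap
    comparator cut-points, and ROC/confusion-matrix evaluation, all wired
    into a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
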