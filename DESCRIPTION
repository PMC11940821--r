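Package: behavcal
Title: Behaviour-Based Calibration of Accelerometer Activity-Count Cut-Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates activity-count intensity thresholds for body-worn
    movement sensors (MotionWatch 8 and ActiGraph GT3X at wrist and hip)
    from direct-observation labelled 30-second epoch counts in preschool
    children. Builds One-vs-Rest and One-vs-One binary classification
    problems over six ordered behaviours, computes ROC curves, selects
    Youden-optimal cut-offs, estimates AUC with DeLong or bootstrap
    confidence intervals, derives a sedentary count range, applies cut-off
    tables to classify epoch time series into intensity classes, and
    compares devices and wear positions by rank correlation and regression.
    Includes a seeded synthetic-cohort generator (Gaussian copula across
    devices, several count-distribution families) parameterised by
    published per-behaviour count moments, so the whole calibration
    pipeline is testable without access to raw child data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
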