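Package: promcat
Title: Adaptive Patient-Reported Outcome Assessment by Computerized
    Adaptive Testing and Regression Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework comparing two ways of shortening
    polytomous patient-reported outcome measures: item response theory
    computerized adaptive testing (partial credit Rasch model, fixed
    quadrature EM calibration, expected a posteriori scoring, minimum
    expected posterior variance item selection) and binary regression
    trees grown by recursive partitioning with 10-fold cross-validated
    cost-complexity pruning, which may additionally split on
    clinician-reported variables. Includes a seeded synthetic cohort
    generator emulating short cleft-related quality-of-life scales, a
    matched-length evaluation harness with the standard accuracy
    metrics (Pearson r, MAE, RMSE, paired Wilcoxon signed-rank on
    squared errors, unique attainable scores), and file round-tripping
    with command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
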