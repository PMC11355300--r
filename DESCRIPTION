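Package: aidalabor
Title: Traffic-Light Risk Zoning and Delivery-Outcome Prediction for
    Dystocic Labor (AIDA)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements the AIDA (Artificial Intelligence Dystocia
    Algorithm) analysis for protracted second-stage labor: traffic-light
    (green/yellow/red) zoning of four intrapartum-ultrasound geometric
    parameters (asynclitism degree, angle of progression, head-symphysis
    distance, midline angle), AIDA class 0-4 risk stratification, pairwise
    decision-tree cut-off derivation, a seeded 70-30 machine-learning
    prediction harness (random forest, support vector machine, multi-layer
    perceptron), and class-stratified NA-aware evaluation that reproduces
    the published per-class performance tables from the published
    per-patient prediction tables. A Gaussian-copula synthetic cohort
    generator emulates the study cohort's marginals, correlation structure
    and outcome mix so every stage is testable without the non-deposited
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
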