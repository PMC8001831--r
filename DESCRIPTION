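Package: gcatriage
Title: Clinical Prediction Rule and Stepwise Diagnostic Algorithm for
    Cranial Giant Cell Arteritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a four-item clinical prediction rule (age > 70,
    new-onset headache, jaw claudication, anterior ischemic optic
    neuropathy) for cranial giant cell arteritis and the stepwise
    diagnostic algorithm that combines the score with C-reactive protein
    and high-resolution temporal artery compression sonography.  Provides
    stratified diagnostic-accuracy statistics (predictive values, ROC/AUC),
    reconstruction of integer 2x2 contingency tables from published
    summary statistics, logistic model derivation with AIC-based
    selection, deterministic constraint-satisfying cohort fixtures, and a
    seeded synthetic cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
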