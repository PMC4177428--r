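Package: riscii
Title: RISC II Trauma Mortality Risk Scoring and Model Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Revised Injury Severity Classification, version II
    (RISC II), a 13-variable categorical logistic score for predicting hospital
    mortality of severely injured patients from AIS-coded injuries, age,
    physiology and admission laboratory values, with missing values handled as
    the reference (zero-effect) category of every predictor.  Provides injury
    severity computations (ISS, NISS, worst/second-worst/head injury), the
    published score table with both rounded score points and full regression
    coefficients, cohort inclusion filtering for trauma-registry tables, the
    score-development methodology (missing-as-reference logistic fits, reference
    fraction enforcement, Nagelkerke R-squared forward selection, weak-category
    merging), evaluation metrics (ROC AUC with DeLong intervals,
    Hosmer-Lemeshow calibration across deciles of risk, precision), and a
    synthetic trauma-registry generator so the full pipeline is testable
    without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
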