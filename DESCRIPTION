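Package: traumaprog
Title: Trauma Prognosis Modelling from Diagnostic Text, Composite Injury
    Scores and Tabular Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seeded analysis pipeline for in-hospital
    prognosis of severe trauma. Free-text admission diagnoses are scored
    against a modular keyword library whose module weights are solved by a
    genetic algorithm maximizing score variance; regional Abbreviated
    Injury Scale (AIS) values are combined into composite severity scores
    by CRITIC objective weighting, equal weighting, or the Injury Severity
    Score (ISS), and the schemes are compared by discrimination,
    calibration and decision-curve analysis. Downstream stages provide
    simulated-imputation selection for missing values, univariate
    screening, SMOTE-ENN rebalancing, tree-ensemble importance screening
    with candidate-set algebra, SHAP direction summaries, backward
    stepwise logistic regression with a nomogram and bootstrap
    calibration, and a nested cross-validated benchmark of binary and
    multiclass classifiers. A synthetic-cohort generator emulating a
    292-patient three-class trauma registry makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    randomForest,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
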