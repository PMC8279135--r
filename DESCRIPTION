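Package: regeval
Title: Regression Evaluation Metrics and Their Informativeness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the informativeness of regression
    evaluation metrics. Implements the coefficient of determination,
    MSE, RMSE, MAE, MAPE, SMAPE and the complementary normalized SMAPE
    (cnSMAPE) with fully specified degenerate-input semantics; a set of
    constructed use cases in which the metrics disagree; a synthetic
    generator for electronic-health-record-like regression datasets
    with an ordinal target; and a repeated-holdout multi-model
    evaluation pipeline that reports per-metric model rankings and
    their agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
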