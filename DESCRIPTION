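Package: nextvisit
Title: Next-Visit Hypertension Risk Prediction from Longitudinal Health Checkups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting whether a health-checkup visitor will
    meet the hypertension criterion (systolic blood pressure >= 130 mmHg or
    diastolic >= 80 mmHg) at their next visit, from an irregular longitudinal
    record of past visits. Provides a synthetic cohort simulator with known
    generative parameters, gap-pruned visit windowing into train/test samples,
    per-visit feature derivation with linear-interpolation imputation and
    zero-padded window encoding, a sorted-split five-fold voting ensemble of
    gradient-boosted trees with per-fold F1-optimal decision thresholds,
    stratified evaluation against a carry-forward baseline, and a virtual-visit
    weight-control counterfactual engine that projects BMI-correlated
    companion factors along gender-specific regression slopes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
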