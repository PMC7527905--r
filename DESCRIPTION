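Package: driftgrade
Title: Automatic Stroke Severity Grading from Wearable Limb-Drift Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic grading of motor weakness in stroke patients
    from wearable tri-axial accelerometer recordings of the four-limb drift
    test. Converts raw acceleration into a limb drift-angle time series via
    quasi-static gravity-vector tilt estimation, extracts kinematic weakness
    features (mean, maximum, oscillation of drift), balances small clinical
    data sets with SMOTE oversampling, trains Bayes-optimized support vector
    machine and tree-ensemble classifiers (AdaBoost, gradient boosting,
    bagging, RUSBoost) with stratified cross-validation, and grades limbs on
    the NIHSS motor item (binary 0/1) and a subdivided MRC muscle-power scale
    (grades 7/8/9), with confusion-matrix, sensitivity/specificity, F1 and
    ROC/AUC evaluation. Includes a grade-conditioned recording simulator and
    the 60-instance clinical feature table used for hold-out evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
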