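Package: haropt
Title: Metaheuristic Wrapper Feature Selection and Hyperparameter Tuning
    for Sensor-Based Human Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection and gradient-boosting hyperparameter
    tuning for inertial-sensor human activity recognition. Implements two
    population metaheuristics, Golden Jackal Optimization and War Strategy
    Optimization, over a mixed 52-dimensional search space (4 XGBoost
    hyperparameters plus a 48-feature binary mask), with fold-wise
    optimization, majority-vote/union consensus aggregation, a repeated
    stratified 70/30 evaluation protocol with macro metrics and one-vs-rest
    AUC, and Shapley-value interpretability (exact subset enumeration for
    small models, TreeSHAP delegation otherwise). Ships statistical feature
    extraction for 6-channel accelerometer/gyroscope windows, a reader for
    the KU-HAR wide CSV layout, and synthetic signal and feature-space
    generators so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
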