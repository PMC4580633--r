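Package: killcluster
Title: GPS Location-Cluster Analysis for Predicting Large-Carnivore
    Feeding Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate feeding-site clusters from GPS collar
    fixes of large carnivores, derives spatio-temporal, activity-sensor
    and ground-truthing-error covariates, fits and selects binomial
    logistic feeding-prediction models by AICc, evaluates them with ROC
    analysis and k-fold cross-validation, and produces
    detection-corrected feeding-event counts with bootstrap intervals.
    Includes a double-observer concordance summary and a synthetic
    biologging simulator (movement states, dual-axis activity,
    satellite-download failure, imperfect ground-truth detection) so the
    whole pipeline can be exercised and validated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
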