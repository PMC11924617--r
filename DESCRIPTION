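Package: gaitDDI
Title: Fall-Risk Assessment from Insole Plantar Pressure with Recessive
    Weak-Foot Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wearable plantar-pressure gait analysis aimed at fall-risk
    screening in older adults. Segments bilateral insole recordings into steps,
    augments them with step-level sliding windows, extracts center-of-pressure
    (COP) features on the functionally weaker foot, and computes the
    Distribution Difference Index (DDI) - the ratio of mean pairwise
    feature-vector distance at a short window length to that at a long window
    length - which flags individuals whose high-risk gait is expressed only
    intermittently (recessive weak foot, RWF). A trainable threshold on the DDI
    routes subjects into RWF/DWF branches of a two-stage classification model
    with per-branch feature selection and classifier tuning, evaluated
    leave-one-subject-out. A synthetic gait simulator with programmable weak
    side, risk effect and episodic switching provides ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    class,
    e1071,
    rpart,
    ranger,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
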