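Package: bloodscore
Title: Abnormal Blood Profile Scoring for Blood-Doping Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies an Abnormal Blood Profile Score (ABPS): a
    calibrated ensemble of a kernel-density naive Bayes classifier and a
    support vector machine over seven hematological markers (HCT, HGB, MCH,
    MCHC, MCV, RBC, RETP), used to flag blood doping in athletes. Also
    computes the OFF-score (HGB x 10 - 60 x RETP), validates and clips
    marker values to physiological ranges, warns about implausible units,
    simulates synthetic athlete cohorts (clean and rhEPO-style doped
    profiles) for training and evaluation, and provides a command-line
    interface for simulate/train/score/offscore workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    kernlab,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
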