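Package: seizr
Title: Age-Independent EEG Seizure Detection with Gaussian SVM and Feature
    Baseline Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete, testable pipeline for automated epileptic seizure
    detection in multi-channel EEG that works across patient ages (neonatal
    and adult). Implements quantitative EEG feature extraction (a versioned
    battery of 103 per-epoch, per-channel features), per-patient feature
    baseline correction (FBC) via estimated optimal detection thresholds,
    Gaussian-kernel support vector machine classification with
    leave-one-patient-out cross-validation and Monte Carlo resampling of
    training data, Kalman-filtered post-processing of classifier outputs,
    and patient-balanced ROC/AUC plus event-based evaluation (false
    detections per hour, seizure detection rate). Includes a synthetic EEG
    cohort generator with per-patient baseline offsets so the whole pipeline
    can be exercised end to end without clinical data, and EDF import/export
    so real recordings can be substituted.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
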