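Package: ecgselect
Title: Costly-Feature Selection for ECG-Based Personal Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrocardiogram (ECG) biometric authentication built
    around classification with costly features. Includes a multi-subject,
    multi-day synthetic ECG cohort generator with ground-truth fiducials, FIR
    bandpass preprocessing, Pan-Tompkins QRS detection with P/Q/S/T
    localization, a 31-feature fiducial feature extractor, SMOTE class
    balancing, a partially observable costly-feature environment with a deep
    Q-network agent, BOHB (Bayesian-optimization hyperband) hyperparameter
    tuning, ReliefF and information-gain baselines, and a cumulative-day
    evaluation protocol reporting accuracy, macro F1 and equal error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
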