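Package: spectralverge
Title: Seizure Prediction from Multiresolution Critical Spectral Verge EEG Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for pre-ictal versus inter-ictal EEG
    classification and seizure-alarm evaluation. Multichannel EEG records
    (EDF/EDF+ with per-channel seizure annotations, or a seeded synthetic
    generator) are segmented and cleaned by multiresolution adaptive
    filtering (wavelet soft-threshold denoising feeding a per-band
    normalized-LMS filter), summarised per band and segment by the Critical
    Spectral Verge - the highest frequency whose spectral power exceeds the
    band mean, refined by a flower-pollination optimizer - and classified by
    a lightweight convolutional neural network. Alarms are scored under
    seizure-prediction-horizon / seizure-occurrence-period semantics with
    sensitivity, accuracy, false-prediction-rate-per-hour and AUC reporting,
    including leave-one-seizure-out and cross-subject protocols and
    class-imbalance resampling (random over/undersampling, borderline
    SMOTE).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
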