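Package: lungsoundr
Title: Lung-Sound Feature Extraction and Asthma Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for classifying asthma from digital-stethoscope lung
    sounds. Generates seeded synthetic respiratory-sound cohorts, segments
    recordings into 3-second clips with spectral quality control, extracts
    Mel-frequency cepstral coefficients and tunable Q-factor wavelet
    transform energy features, selects features with ReliefF, and evaluates
    quadratic-kernel SVM and narrow neural-network classifiers under
    participant-level stratified 10-fold cross-validation with a full
    metric panel and ROC/PR curves.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
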