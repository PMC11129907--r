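Package: tremorkit
Title: Wearable-Sensor Tremor Severity Classification for Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for classifying parkinsonian rest-tremor
    severity from wrist- and ankle-worn inertial measurement units (IMUs)
    sampled at 50 Hz. Raw 6-channel windows (triaxial accelerometer and
    gyroscope) preceding clinician score entries are band-filtered into
    tremor (3.5-7.5 Hz) and voluntary-movement (0.5-3 Hz) components,
    summarised by a continuous-wavelet tremor-band energy series and a
    90-feature catalog (time-domain, spectral and nonlinear features),
    ranked by mutual information with the clinical label, rebalanced by
    random undersampling and SMOTE, and classified with a radial-basis
    support vector machine. A synthetic-session generator emulates
    free-living recordings with realistic label imbalance so that every
    stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
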