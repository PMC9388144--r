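Package: hybridbci
Title: Multimodal EEG-fNIRS Fusion with Multi-Domain Features and Progressive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hybrid electroencephalography (EEG) and functional
    near-infrared spectroscopy (fNIRS) brain-computer interface analysis.
    Implements the full decoding chain for two-class paradigms (motor imagery,
    mental arithmetic): signal preprocessing (common average reference,
    Chebyshev-II and zero-phase Butterworth band-pass filtering, rational-rate
    resampling, the modified Beer-Lambert law, epoching and 1-second subtask
    segmentation), multi-domain feature extraction (time-domain statistics,
    differential entropy, periodogram power spectral density), Z-score
    normalisation, wrapper feature selection by atom search optimisation, and
    decision-level fusion by two-stage stacked (progressive) learning with four
    primary learners and a logistic-regression meta-learner. A seedable
    synthetic generator of paired EEG and dual-wavelength fNIRS recordings
    makes the whole pipeline reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    withr,
    generics,
    ggplot2,
    signal,
    ranger,
    xgboost,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
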