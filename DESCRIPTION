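Package: eegdem
Title: EEG Complexity Features for Discriminating Dementia Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating Alzheimer's disease,
    frontotemporal dementia, and healthy controls from resting-state
    multichannel EEG. Recordings are segmented into overlapping one-second
    windows, five complexity measures (singular-value-decomposition entropy,
    Higuchi fractal dimension, zero-crossing rate, detrended fluctuation
    analysis, and Hjorth parameters) are computed per channel and window, and
    binary classification tasks are evaluated with subject-disjoint
    train/test splits, subject-wise cross-validation, and minority-class
    oversampling. Per-channel importance scores from the fitted models are
    rendered as 10-20 montage scalp topomaps. A synthetic cohort generator
    with class-conditional spectral structure makes the whole pipeline
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
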