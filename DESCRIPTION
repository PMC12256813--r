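Package: sinkindex
Title: Sink-Index EEG Markers from Linear Time-Varying Dynamic Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates subject-specific linear time-varying dynamic network
    models from multichannel resting-state scalp EEG by windowed least
    squares, computes per-channel sink indices from rank-normalized row and
    column norms of the state-transition matrices, and aggregates them into
    a frontal-temporal versus central-parietal-occipital ratio marker for
    dementia phenotyping. Includes EDF, EEGLAB and CSV ingestion with a
    Butterworth preprocessing chain, spectral band-power, Hjorth and
    wavelet baseline features, one-vs-rest leave-one-out classification
    with micro-averaged ROC curves, nonparametric group statistics, and a
    seeded synthetic-cohort generator with planted source-sink structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    rpart,
    randomForest,
    nnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
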