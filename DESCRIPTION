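Package: microstatr
Title: Resting-State EEG Microstate Analysis with a Synthetic Cohort Generator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation of multichannel resting-state EEG into microstates
    by polarity-invariant modified K-means clustering of global-field-power
    peak topographies, with back-fitting, short-segment smoothing, per-map
    duration/occurrence/coverage/GEV statistics, transition ("syntax")
    analysis with a permutation test against occurrence-predicted
    transitions, covariate-adjusted group comparison (ANCOVA with
    Benjamini-Hochberg FDR), and leave-one-out cross-validated
    classification.  Includes a semi-Markov synthetic EEG cohort generator
    with planted microstate structure so every stage is testable by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    nnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
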