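Package: neowave
Title: Waveform Quantification of Neonatal EEG Seizure Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the waveform morphology of neonatal seizure EEG
    beyond amplitude trends. Implements three per-epoch markers computed
    from the Hilbert analytic signal: the complex envelope (median
    instantaneous amplitude), epileptic sharpness (median voltage drop
    7 ms either side of adaptively detected extrema), and the degree of
    nonlinearity (standard deviation of the instantaneous frequency
    normalized by the zero-crossing frequency). Includes EDF ingest with
    longitudinal bipolar montage derivation, multi-rater seizure
    annotation fusion, the preprocessing chain (out-of-range correction,
    notch, high-pass, z-scoring, PCA denoising), seizure stage
    segmentation, mixed-model group statistics with Tukey post hoc
    tests, single-feature classification (SVM, kNN, logistic
    regression, naive Bayes) with ROC and calibration analysis, and a
    seeded synthetic-EEG generator for end-to-end testing without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    class,
    e1071,
    emmeans,
    graphics,
    jsonlite,
    lme4,
    lmerTest,
    pROC,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
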