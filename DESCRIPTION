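Package: femgxdyn
Title: Facial EMG Expression Dynamics: Simulation, Classification, and
    Workload Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis pipeline for multi-channel facial
    electromyography (fEMG) amplitude recordings: a seeded synthetic cohort
    generator with FACS-consistent muscle activation, two-stage physiological
    normalization (neutral correction and MVIC scaling), fixed-length window
    segmentation, a CNN-TCN facial expression classifier (plus CNN, TCN,
    LSTM, CNN-LSTM and GRU baselines) evaluated under leave-one-participant-out
    cross-validation, inference of continuous expression sequences over task
    scenes, an 81-feature taxonomy of categorical expression dynamics
    (run-length bursts, transition matrices, entropy, dominance, latency), and
    mixed-effects association of those features with NASA-TLX workload ratings
    under Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
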