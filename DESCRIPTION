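Package: epihfo
Title: Detection, Weakly Supervised Classification and Reverse Engineering
    of Epileptogenic High-Frequency Oscillations in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolbox for interictal high-frequency oscillation
    (HFO) analysis in intracranial EEG. Provides a short-term-energy candidate
    detector (80-500 Hz band, RMS and peak thresholds in units of standard
    deviations), image encodings of each detected event (Gabor-wavelet
    scalogram, EEG tracing plot and amplitude-coding plot), compact
    convolutional neural-network classifiers for artefact rejection and spike
    co-occurrence, a weakly supervised training protocol that distills
    epileptogenic HFOs from channel resection status and post-operative
    seizure outcome, perturbation-based interpretation of the trained model
    (time-frequency template statistics, inverted-T mask perturbation and
    spike-template insertion), outcome-level evaluation (resection ratios,
    rank-based ROC/AUC, logistic outcome models, rate comparisons), and a
    reproducible synthetic iEEG cohort generator so the full pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    zoo,
    pROC,
    glmnet,
    optparse
Config/testthat/edition: 3
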