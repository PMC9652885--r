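Package: eegmontage
Title: Optimal Bilaterally Symmetric EEG Electrode Montages for MCI
    Screening
Version: 0.1.0
Authors@R:
    person("EEG Montage", "Developers", email = "eegmontage@example.org",
           role = c("aut", "cre"))
Description: Tools for finding small, bilaterally symmetric resting-state
    EEG electrode montages that preserve machine-learning discrimination
    between mild cognitive impairment (MCI) and healthy controls.
    Implements the full analysis chain: zero-phase Butterworth band-pass
    preprocessing with amplitude-based epoch rejection; ten candidate
    feature families per channel (absolute and relative band power in
    nine sub-bands, inter-hemispheric differential and rational
    asymmetry, envelope-coherence phase-amplitude coupling, Shannon
    entropy, Hjorth parameters, largest Lyapunov exponent, Hurst
    exponent, Lempel-Ziv complexity); exhaustive enumeration of
    symmetric electrode configurations; leave-pair-out cross-validated
    SVM evaluation with per-fold z-scoring and Fisher-score feature
    selection; device-comparison statistics; and a synthetic two-group
    cohort generator for end-to-end calibration when clinical data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
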