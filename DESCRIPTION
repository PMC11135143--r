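Package: hfokit
Title: High-Frequency Oscillation Detection and Classification for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for high-frequency oscillation (HFO) analysis in
    intracranial EEG: calibrated EDF reading, Chebyshev type-II band-pass filtering
    realized as stable second-order sections, short-time-energy (STE) and MNI-style
    event detection with channel-parallel execution, compact convolutional
    artifact/spike classification of detected events with multiply-accumulate (MAC)
    accounting and structured pruning, detector-concordance evaluation via interval
    overlap ratios, and a seeded synthetic iEEG simulator with ground-truth event
    labels that makes every stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
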