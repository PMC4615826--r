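Package: drowsyTE
Title: Transfer-Entropy Effective Connectivity for Drowsy-Driving EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking behavioral vigilance to directed EEG
    connectivity in sustained-attention driving studies. Implements the
    logistic driving-performance (DP) index derived from reaction times,
    Kraskov-style k-nearest-neighbor transfer entropy between channel
    pairs (with Cao embedding selection, Theiler exclusion and surrogate
    significance testing), Granger-causality and FFT band-power reference
    measures, a DP-sorted moving-window statistical pipeline with
    rank-sum tests and false-discovery-rate control, and a synthetic
    session generator with known ground-truth couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
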