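Package: cfcnet
Title: Genuine Cross-Frequency Coupling Networks from Multichannel
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of genuine interareal cross-frequency coupling (n:m
    cross-frequency phase synchrony and phase-amplitude coupling) in
    multichannel electrophysiological recordings such as stereo-EEG or
    source-reconstructed MEG. Provides a Morlet filterbank with artifact
    rejection, phase-synchrony estimators (PLV, wPLI), surrogate-based
    edge significance, triangle-motif pruning of potentially spurious
    cross-frequency edges, network-topology statistics (directed hubness,
    distance bins, laminar-depth groups), a peak-locked single-pair
    evidence procedure, a synthetic-recording generator with labelled
    ground truth, and a four-population Kuramoto phase-oscillator model
    for validating the pruning procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
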