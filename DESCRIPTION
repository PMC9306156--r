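Package: hdemg
Title: High-Density Surface EMG Simulation, Channel Selection and Online
    Gesture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying hand-gesture recognition from high-density
    surface electromyography (HD-EMG) under changing wrist positions and
    contraction levels. Provides a physiologically motivated simulator of
    256-channel forearm HD-EMG sessions (gesture-specific spatial hot spots,
    wrist-dependent map shifts, trapezoidal activation profiles), standard
    preprocessing (band-pass filtering, RMS envelopes, MVC normalisation,
    contraction segmentation), Hudgins-style time-domain feature extraction,
    shrinkage linear discriminant analysis, sequential forward channel
    selection with parent-channel mapping, circumferential electrode
    placement, Bhattacharyya class-separability indices, and a closed-loop
    simulation of an online dwell-time control task with completion-rate,
    completion-time and dwelling outcome measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
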