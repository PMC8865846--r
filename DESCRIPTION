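Package: swrnet
Title: Sharp Wave-Ripple Generation and Sequence Replay in a Learned
    Recurrent Hippocampal Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the emergence of hippocampal sharp wave-ripples and
    bidirectional place-cell sequence replay from structured recurrent
    excitation in a CA3-like spiking network. Provides a synthetic
    exploration stage (theta-modulated, phase-precessing inhomogeneous
    Poisson place-cell spike trains on a linear track), pair-based
    spike-timing-dependent plasticity with symmetric or asymmetric kernels
    for learning sparse recurrent weights, an adaptive exponential
    integrate-and-fire network simulator with conductance synapses, a
    synaptic-current local field potential estimate with Welch spectra,
    Fisher g-test peak significance and Morlet wavelet maps, and a
    memoryless Bayesian place decoder with constant-velocity path fitting
    and shuffle-based replay significance, plus the structural network
    perturbations (weight scaling, binarization, column shuffling,
    non-adapting cells, interneuron-only variants) used to dissect the
    mechanisms of ripple generation and replay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
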