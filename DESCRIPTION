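Package: ptxgrape
Title: Calibration-Free Parallel-Transmit GRAPE Pulse Design for
    Spectrally Selective Excitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Optimal-control (GRAPE) design of universal parallel-transmit
    (pTx) radiofrequency and gradient waveforms for slice- and slab-selective
    excitation at ultra-high field. Provides a multi-channel hard-pulse Bloch
    simulator with analytic adjoint gradients, a magnitude-least-squares cost
    with a linear-phase consistency term evaluated at per-voxel random
    frequency offsets, constrained waveform optimization against scanner
    hardware limits (peak voltage, per-channel and total average power,
    gradient amplitude and slew rate), a synthetic multi-subject B1+/deltaB0
    head-model generator for universal-pulse design studies, extended phase
    graph (EPG) simulation of variable-flip-angle turbo-spin-echo trains, and
    evaluation utilities (spectral responses, slice profiles, slice
    integrals, flip-angle NRMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
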