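Package: foxdyn
Title: Backbone Dynamics and Interaction Analysis of FOXO Forkhead Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing the structure and backbone
    dynamics of FOXO-family forkhead (FH) domains. Fits 15N spin-relaxation
    decays (R1, R1rho) with pooled duplicate-delay noise estimation and
    Monte-Carlo error propagation, applies the off-resonance tilted-field
    correction to obtain R2, computes steady-state 15N{1H} heteronuclear NOE
    values with propagated errors, maps chemical-shift perturbations and
    cross-homolog shift correlations, classifies titration responses
    (weak/strong CSP versus line broadening), performs backbone Kabsch
    superposition with RMSD/RMSF and named distance monitors, and scans
    sequences and structures for W-[2-5]-[S/T/C/Y] tryptophan-interaction
    motifs with their distance/angle geometry. A synthetic-data generator
    with known ground truth exercises every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
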