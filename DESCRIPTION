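Package: wbnm
Title: Resting-State Whole-Brain Network Modeling with Coupled Wendling
    Neural Masses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates resting-state whole-brain activity by coupling
    Wendling neural-mass nodes (one per cortical region of the
    Desikan-Killiany parcellation) through a max-normalized structural
    connectivity matrix rescaled by a global coupling coefficient.
    Provides a fixed-step fourth-order Runge-Kutta integrator driven by
    per-step Gaussian input, phase-locking-value (PLV) functional
    connectivity via the Hilbert transform, fitting of the global
    coupling coefficient by Pearson correlation against a reference
    functional connectivity matrix, per-region signal descriptors
    (power spectrum, dominant frequency, baseline potential), and
    graph-theoretic characterization of thresholded networks (degree,
    characteristic path length, clustering, global efficiency,
    small-world index against random reference networks). Includes a
    synthetic-connectome generator with hemispheric block structure so
    the full analysis chain is testable without empirical MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
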