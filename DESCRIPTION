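Package: fancircuit
Title: Quantitative Analysis of Fan-Cell Inputs to Medial Entorhinal Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for circuit-mapping analyses of lateral-to-medial entorhinal
    cortex fan-cell projections in current-clamp recordings. Extracts intrinsic
    membrane properties (input resistance, membrane time constant, sag,
    rheobase, action-potential features, impedance resonance from ZAP
    protocols), characterises optogenetically evoked excitatory and inhibitory
    postsynaptic potentials including excitation-inhibition ratios, response
    classification and 10/20 Hz train dynamics, quantifies volumetric synaptic
    puncta density and laminar fluorescence-intensity profiles, and provides
    from-scratch nonparametric rank statistics (Friedman with Kendall's W,
    exact Wilcoxon signed-rank, Mann-Whitney U, Kruskal-Wallis with eta
    squared, Dunn post-hoc, two-sample Kolmogorov-Smirnov) plus simple linear
    regression with an F-test. A seeded conductance-style simulator of
    resonant membranes, synaptic kernels, cohorts, puncta fields and intensity
    profiles supplies ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    withr
Config/testthat/edition: 3
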