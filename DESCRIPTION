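Package: spheroidsim
Title: Hybrid Stochastic Cell-Lattice and Reaction-Diffusion Simulation of
    Multicellular Tumor Spheroid Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of avascular multicellular tumor spheroid
    (MCTS) growth on an unstructured three-dimensional lattice, coupled to
    steady-state reaction-diffusion fields for glucose, oxygen, lactate,
    extracellular matrix and necrotic waste. Cell-cycle progression, growth
    with pushing, division, quiescence, death and lysis are advanced by an
    exact stochastic simulation (Gillespie) algorithm; four nested growth
    control variants (glucose-oxygen product threshold, ATP threshold,
    lactate-induced death, waste/hypoxia-mediated quiescence) are selectable
    at run time. Includes a cross-inhibited Michaelis-Menten glucose/oxygen
    metabolism model with ATP and lactate bookkeeping, virtual Ki67/TUNEL/ECM
    radial profiling, Gaussian likelihood and AIC model scoring, and a
    quantitative section-image analysis toolbox (median filtering, watershed
    nuclei segmentation, marker classification, discrete Voronoi cell sizing)
    with a synthetic ground-truth image generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
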