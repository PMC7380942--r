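Package: RhoRacWaves
Title: Reaction-Diffusion Modelling of the RhoA-Rac1 GTPase Network in
    Migrating Cells
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a five-variable RhoA-Rac1-DIA-ROCK-PAK signalling
    network model of mesenchymal cell migration: well-mixed kinetics with
    hyperbolic regulatory multipliers, steady-state enumeration and
    stability classification, two-parameter bifurcation atlases over
    effector abundances, a quasi-steady-state phase-plane reduction,
    reaction-diffusion simulation on 1-D abundance profiles and 2-D
    rasterized cell masks with graded DIA/ROCK totals, kinase-inhibitor
    models (IPA-3, Y-27632), and analysis tools for activity bursts,
    kymographs, oscillatory centers, PAK hysteresis protocols, and
    synthetic imaging data (pseudo-FRET movies, PLA-like point patterns).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    Matrix,
    Rcpp,
    yaml,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
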