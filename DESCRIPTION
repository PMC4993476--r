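Package: vasox
Title: Synthetic Tumor Vasculature, Network Hemodynamics and Coupled Oxygen Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulator of synthetic arterio-venous blood vessel
    networks in normal and tumorous tissue. Generates lattice-based host
    vasculature from configurable root-node geometries, remodels it under
    tumor growth (angiogenic sprouting, circumferential dilatation, wall
    degeneration, collapse and regression, solid-stress compression),
    solves network hemodynamics with the Fahraeus-Lindqvist apparent
    viscosity and hematocrit phase separation at bifurcations, and couples
    intravascular oxygen advection (Hill binding) to tissue diffusion with
    Michaelis-Menten consumption via a fixed-point finite-element scheme.
    Computes the tissue-level observables used to interpret optical
    mammography: total and oxygenated hemoglobin concentration, tissue
    blood oxygen saturation, perfusion, and oxygen extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
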