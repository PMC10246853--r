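Package: nervestim
Title: Model-Based Design of Peripheral Nerve Stimulation Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale simulator for the model-based design of peripheral
    nerve stimulation electrodes. Generates synthetic multi-fascicle nerve
    anatomy, builds parametric electrode models (clinical quadripolar leads,
    multipolar cuffs, transversal intrafascicular arrays, and a radially
    symmetric hybrid surface/intrafascicular design), solves the anisotropic
    volume-conduction problem with fiber-aligned conductivity on rectilinear
    finite-volume grids, computes myelinated-axon recruitment thresholds with
    a double-cable membrane model and a fast reduced variant, and evaluates
    fascicular, axonal, and geometric selectivity together with invasiveness,
    adaptability, and repeatability benchmarks. Includes grid-search
    optimization of electrode dimensions driven by a cheap geometric
    selectivity surrogate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    mclust,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
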