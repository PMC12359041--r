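Package: nucmech
Title: Polymer-Physics Simulation of Chromatin-Based Nuclear Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin dynamics of a cell-nucleus model: triblock
    chromatin copolymers confined in a bead-spring polymeric lamina shell, with
    optional chromatin-lamina tethering and intra-heterochromatin crosslinking.
    Provides micromanipulation-style force spectroscopy protocols (axial
    stretching, uniaxial plate compression), nuclear spring-constant estimation,
    and genomic readouts (simulated DamID lamina-contact profiles, LAD
    percentages, contact-frequency P(s) curves and deformation-change metrics),
    together with a seeded, config-driven pipeline for replicate sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
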