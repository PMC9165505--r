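Package: dfnematic
Title: Dual-Frequency Nematic Modelling and Quantification of Endothelial
    Monolayer Flow Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to model and quantify the adaptation of endothelial
    monolayers to fluid flow by analogy with dual-frequency nematic liquid
    crystals.  Provides a Debye-type frequency-dependent dielectric
    anisotropy model with zero-crossing and Freedericksz-threshold
    utilities, a 2D lattice Landau-de Gennes Q-tensor relaxation simulator
    supporting rod-like/disk-like (healthy/senescent) particle mixtures and
    frequency-switch protocols, and a monolayer quantification pipeline:
    equivalent-ellipse cell shape metrics and nematic order parameter,
    planar-cell-polarity (nucleus to Golgi) indices via Voronoi assignment,
    velocity-correlation-length estimation and substrate strain energy.
    Seeded synthetic-data generators with known ground truth stand in for
    unreleased microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
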