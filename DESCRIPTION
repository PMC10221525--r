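Package: droplamp
Title: Droplet-Microfluidic Chip Simulation and Digital-LAMP Partition Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing droplet-generation microfluidic chips and for
    quantifying digital loop-mediated isothermal amplification (digital-LAMP)
    assays. Includes a two-dimensional incompressible two-phase flow solver
    (Chorin projection on a staggered grid coupled to a conservative level-set
    interface model with continuum-surface-force surface tension and wall
    contact angles), constructors for the standard channel layouts
    (flow-focusing and T-junctions, linear/serpentine buffers, spiral and
    splitting collection paths), droplet detection and effective-diameter and
    generation-frequency metrics, scripted design-sweep experiments, and
    Poisson-partition statistics for droplet digital assays (concentration
    estimation, serial-dilution calibration, limit-of-detection curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
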