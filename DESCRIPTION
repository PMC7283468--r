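Package: mechamigr
Title: Discrete-Element Simulation of Mechanosensitive Single-Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a polarized, deformable 3D cell migrating on a flat
    elastic-ligand substrate using the discrete element method. The cell cortex
    is a closed triangulated shell with viscoelastic edges, area, volume and
    bending elasticity; migration emerges from a globular-actin polarity field
    driving lamellipodial protrusion, stochastic focal adhesions modeled as
    two-spring catch-like bonds, and contractile stress fibers that strengthen
    stepwise when their contraction stalls. Two switchable mechanosensing
    mechanisms (focal-adhesion maturation and stress-fiber strengthening) let
    the model reproduce progressive (keratocyte-like) versus collective
    (load-and-fail) rear retraction across substrate stiffness and
    receptor-ligand affinity, with traction maps, migration-mode
    classification, and parameter-study aggregation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
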