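Package: embryophase
Title: Phase-Field Simulation of Early Caenorhabditis elegans Embryogenesis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional multicellular phase-field simulator for the
    early (1- to 8-cell) Caenorhabditis elegans embryo. Each cell is a smooth
    scalar field confined in a rigid, optionally compressed eggshell and
    driven by surface tension, cell-eggshell and cell-cell repulsion,
    pairwise cell-cell attraction, and a volume constraint, integrated with
    an explicit advective scheme. Cell divisions are instantaneous plane
    bisections with prescribed orientation and volume ratio, triggered when
    the embryo's root-mean-square cell velocity reaches a local minimum
    (quasi-steady state). The package ships a self-contained scenario
    library (wild-type compressed and uncompressed programs, attraction and
    orientation scans) and a morphometrics layer: surface and contact areas,
    contact maps with conserved-contact classification across replicates,
    cell deformation coefficients, developmental-path signatures,
    planarization width, and simulation-to-experiment time-scale fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Spatial, MathematicalBiology
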