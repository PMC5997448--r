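Package: chiratube
Title: Cell-Based 3D Vertex-Model Simulation of Chiral Epithelial Tube Twisting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the twisting of an epithelial tube driven by intrinsic
    cell chirality, using a cell-based vertex model for a curved polygonal
    sheet in three dimensions. Builds a model tube of polygonal cells by
    periodic Voronoi tessellation wrapped onto a cylinder, imprints chiral
    cell shapes by polarity-directed anisotropic edge contraction, relaxes
    the tissue by overdamped gradient dynamics (fixed-step Runge-Kutta) with
    T1-type vertex reconnection, and quantifies the outcome: tube twist
    angle, momental-ellipse cell-axis and deviation statistics, edge-angle
    distributions, directional cell sliding, boundary tilting, and cell
    intercalation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
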