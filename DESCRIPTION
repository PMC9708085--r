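Package: embryodiv
Title: Division-Plane Topology and Geometry in Early Plant Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the variability of cell-division planes in early
    Arabidopsis embryos on segmented 3D label images. Implements a
    lineage-based cell-shape topology descriptor (number of division faces)
    with shape-class entropy, a graph-cut theory of polyhedral cell division
    topology, a stochastic voxel model of division-plane positioning by
    Metropolis interface-area minimization, and scoring machinery that
    compares simulated to observed divisions. A synthetic-embryo generator
    reproduces the stereotyped first four division generations and
    configurable variable divisions beyond, so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
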