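Package: wnes
Title: Weighted Nodes-and-Edges Tests for Two-Group Differences of Directed
    Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical comparison of a directed acyclic biological network
    (gene regulatory, signalling or systems-epidemiology network) between two
    groups of subjects, such as cases and controls.  Implements the weighted
    nodes-and-edges statistic WNES, which combines squared standardized
    differences of node means and of edge regression coefficients and
    up-weights nodes with many descendants, together with its companions NES
    (unweighted), NS (nodes only), ES (edges only) and the aligned-rank test
    RT.  Significance is assessed by group-label permutation.  A linear
    Gaussian structural equation model simulator with variance rectification,
    scenario builders for node, edge and edge-direction perturbations, and a
    Monte-Carlo harness for type-I-error and power calibration are included,
    along with readers for edge-list and GraphML network files and delimited
    data matrices and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
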