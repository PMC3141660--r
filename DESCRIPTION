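Package: quartetdist
Title: Sub-Cubic Quartet Distance Between General Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the quartet distance between two unrooted
    phylogenetic trees whose inner nodes may have any degree, using a
    counting scheme over pairs of directed inner edges whose per-pair
    cost is reduced to constant time by precomputed subtree-intersection
    aggregates and dense matrix products. Includes an exact brute-force
    quartet-enumeration oracle, seeded generators for benchmark tree
    topologies (random binary, random multifurcating, star, and
    hub-and-spoke trees), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
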