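Package: ncutphylo
Title: Phylogenetic Reconstruction by Recursive Normalized Min-Cut of
    Similarity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein similarity graphs from normalized pairwise
    local-alignment bit scores and reconstructs phylogenetic tree topologies
    by recursively bipartitioning the graph. Each bipartition is found by
    solving a cardinality-constrained minimum-cut as a quadratic binary
    (QUBO) objective -- with exhaustive and simulated-annealing backends --
    and post-processing the constrained cuts into the normalized cut (Ncut)
    criterion of Shi and Malik. Includes a simulation suite (random and Yule
    trees, WAG+Gamma+I protein evolution with power-law indels), baseline
    bipartitioners (spectral, k-means, Ward), and graph/cluster statistics
    (NMI, transitivity, p-distance) for benchmarking cut quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
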