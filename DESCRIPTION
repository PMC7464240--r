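Package: commnet
Title: Communicative Gene Discovery from Expression and Protein-Protein
    Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies highly communicative genes in case/control
    transcriptomes by combining paired-design empirical-Bayes moderated
    t differential expression with protein-protein interaction network
    topology. Provides native implementations of the micro-level
    centrality metrics (degree, stress, betweenness, closeness,
    eigenvector), greedy Louvain-style modularity optimisation,
    centrality-threshold gene prioritisation at the whole-network and
    per-module level, intra- and inter-module subnetwork extraction and
    hypergeometric gene-set over-representation, together with a
    synthetic-data generator emulating paired lesional/non-lesional
    microarray designs and planted-module interaction networks so the
    whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    withr,
    fgsea,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
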