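Package: hiersys
Title: Hierarchical Protein System Discovery and Selective-Pressure Scoring
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds multi-level hierarchies of protein systems from protein
    affinity graphs with a supervised hierarchical graph neural network
    (an MPGNN variant of the Hi-LANDER linkage/density clustering model),
    then scores each system for selective pressure from gene-level signals
    (mutation burden, meta-survival z-scores, perturbation or dependency
    scores) with a nonnegative group-lasso path and permutation FDR.
    Includes clustering agreement metrics (pairwise F, BCubed F, NMI),
    ontology-format hierarchy I/O, significance-guided pruning, Cytoscape
    export, and a fully seeded synthetic-data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
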