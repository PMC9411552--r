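Package: rmethpred
Title: Balanced-Ensemble Prediction of RNA-Methylation-Associated Genes
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts genes functionally associated with RNA methylation from
    one-hot gene-attribute matrices using ensembles of binary classifiers
    trained on balanced negative-sampling sets, aggregates probabilities
    genome-wide, and validates predictions orthogonally on protein-protein
    interaction networks via personalized PageRank, preranked gene-set
    enrichment analysis, and Louvain community detection with hypergeometric
    over-representation.  Ships a synthetic-data generator with planted
    class-conditional feature signal and stochastic-block-model networks so
    the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
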