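Package: biokg
Title: Metapath Embeddings of Heterogeneous Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds typed biomedical knowledge graphs from standardized binary
    edge datasets, collapses multi-step metapaths into degree-weighted path
    count (DWPC) source-target networks, embeds them with weighted random
    walks and a skip-gram model, and evaluates the embeddings by network
    reconstruction AUROC, orthogonal-network recapitulation, co-rank
    empirical P values and permutation-null fold-change/FDR analysis.
    Includes standardization utilities for omics inputs (expression
    signature binarization, waterfall drug-sensitivity binarization,
    ontology propagation and information-content pruning, TF-IDF
    cross-reference mapping) and seeded synthetic fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    limma,
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
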