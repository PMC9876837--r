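Package: MetageneNMF
Title: Metagene Discovery from Two-Group Expression Data via Nonnegative
    Matrix Factorization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for extracting metagenes, groups of genes with
    correlated expression, from two-group (case versus control) expression
    matrices. Differentially expressed genes are selected with a moderated
    t-statistic and Benjamini-Hochberg adjustment, factorized by nonnegative
    matrix factorization with multiplicative updates, and the factorization
    rank is chosen automatically from the residual-sum-of-squares curve by a
    unit-invariant knee point. Metagene member genes are screened with the
    Kim-Park entropy score, characterized by hypergeometric
    over-representation against gene-set collections, and prioritized through
    interaction-network hub ranking (degree and betweenness). A second
    dataset can be used to validate shared hub genes. A synthetic-data
    generator with planted differential expression, planted low-rank factor
    structure and planted network hubs makes every stage testable against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
LinkingTo: Rcpp, RcppArmadillo
biocViews: GeneExpression, DifferentialExpression, Network, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
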