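Package: malani
Title: Machine Learning-Assisted Network Inference for Coordinator Gene
    Discovery in Cancer Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the MALANI (Machine Learning-Assisted Network
    Inference) procedure for discovering cancer-associated gene pairs from
    labelled expression matrices without assuming differential expression or
    mutation. Gene pairs are scored by the cross-validated performance of
    support vector machines trained on per-sample expression products, in
    three stages: gene-wise screening to a selected set, pair-wise partner
    search, and an ensemble feature-selection vote that yields an inferred
    network (MIN). Downstream tools classify network genes into Class I
    (differentially expressed or mutated) and Class II (neither), detect
    hubs, expand networks along shortest protein-protein interaction paths
    (PIE-MIN), summarise mutation landscapes, perform hypergeometric gene-set
    enrichment, and evaluate models by Monte-Carlo permutation testing. A
    synthetic-data module generates labelled expression data with planted
    fold-change genes and differential-correlation coordinator pairs,
    scale-free interaction graphs, and mutation tables with machine-readable
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    igraph,
    randomForest,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
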