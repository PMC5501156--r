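Package: exprgraph
Title: Microarray Expression Analysis Materialized into a Property Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained transcriptome analysis workflow for single-factor
    microarray designs: quantile normalization and median-polish summarization,
    expression-set assembly, empirical-Bayes moderated t differential
    expression with Benjamini-Hochberg FDR and fold-change selection,
    Pearson-dissimilarity clustering (hierarchical and native k-medoids),
    hypergeometric over-representation analysis, and materialization of all
    results into a typed property graph (genes, protein-protein interactions,
    clusters, biological-process terms, experiments, hubs) with GraphML, JSON
    and Cypher-script persistence, native traversal queries (schema summary,
    hub ranking by qualifying PPI degree, cross-experiment co-expression), a
    data-derivation provenance recorder, a synthetic-data generator with
    controlled ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    SummarizedExperiment,
    S4Vectors,
    cluster,
    digest,
    jsonlite,
    xml2,
    yaml,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
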