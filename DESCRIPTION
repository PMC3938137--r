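Package: dmakit
Title: Microarray Expression Analysis Toolkit: Normalization, Differential
    Expression, Enrichment, Clustering and RT-qPCR Primer Design
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable re-implementation of a classic microarray analysis
    workbench: quantile normalization, detection/intensity/variance probe
    filtering with all-samples-fail retention semantics, two-group volcano
    differential expression and time-series trend ranking by Pearson
    correlation against the sample-order ramp, exact hypergeometric
    over-representation tests for flat gene-set collections and for the Gene
    Ontology DAG with true-path annotation propagation, hierarchical and
    k-means clustering, EM-fitted probabilistic PCA tolerant of missing
    values, and RT-qPCR primer enumeration with Tm, GC, homopolymer, hairpin
    and dimer screening. Includes seeded synthetic-data generators for every
    input class and a thin command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
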