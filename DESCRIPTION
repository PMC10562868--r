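Package: ripclust
Title: Integrative RIP-Seq Enrichment, Clustering and mRNA Cohort
    Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for integrating RNA
    immunoprecipitation sequencing (RIP-seq) experiments across many
    RNA-binding factors. Implements paired IP-versus-total
    negative-binomial enrichment testing, transcript filtering to an
    analysis universe, assembly of a gene-by-factor log2 fold change
    matrix, correlation-distance UPGMA of experiments and k-means
    partitioning of mRNAs into interaction-profile cohorts, per-cluster
    property comparisons against the all-gene distribution
    (Mann-Whitney with FDR correction, notched box summaries), 5'UTR
    adenosine composition and positional enrichment profiles, tRNA
    adaptation index codon metrics, and hypergeometric / Monte-Carlo
    gene-set overlap statistics. Includes a synthetic-data generator
    that plants known interaction-profile clusters so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    edgeR,
    limma,
    ape,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
biocViews: Sequencing, RIPSeq, Clustering, GeneExpression,
    DifferentialExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
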