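Package: coexnet
Title: Gene Co-Expression Networks from RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for building gene co-expression
    networks from bulk RNA-seq data: parses GFF3 gene models and selects
    the longest splice variant per gene, counts reads per gene from SAM
    alignments with unambiguous union-mode assignment and HTSeq-style
    special counters, aggregates per-sample count files into an m x n
    expression matrix, normalizes to TPM and RPKM, flags low-quality
    samples from mapper summaries and coding fractions, computes all-pairs
    Pearson correlations blockwise, thresholds them into a weighted
    network, partitions the network with the Markov Cluster (MCL)
    algorithm, and provides network and sample diagnostics (degree
    distributions, power-law fits, PCA, hierarchical sample clustering).
    A synthetic-data generator plants co-expression modules in
    negative-binomial count matrices so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
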