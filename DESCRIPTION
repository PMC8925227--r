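Package: stresslnc
Title: Discovery and Regulatory-Network Analysis of Heat-Responsive lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested re-implementation of a bulk RNA-seq
    workflow for identifying heat-stress-responsive long non-coding RNAs
    (lncRNAs) and their regulatory context in a two-condition, three-replicate
    design. Provides a filter cascade for lncRNA discovery (length, coding-gene
    overlap, expression floor, and a three-predictor coding-potential
    consensus), strand-aware positional classification (lincRNA, intronic,
    antisense), FPKM computation and replicate correlation, a negative-binomial
    conditional exact test for differential expression with
    Benjamini-Hochberg adjustment, cis (genomic window) and trans (expression
    correlation) target prediction with common-target intersection,
    hypergeometric over-representation analysis, miRNA-lncRNA complementarity
    expectation scoring, and assembly/export of the miRNA-lncRNA-gene-term
    regulatory network. A synthetic-data generator with planted ground truth
    (toy genome, annotations, negative-binomial counts, embedded miRNA sites,
    term maps) makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
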