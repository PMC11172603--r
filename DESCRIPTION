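Package: stresslnc
Title: Identification and Stress-Response Analysis of Long Noncoding RNAs
    in Rice Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a long noncoding RNA (lncRNA)
    discovery and stress-response pipeline for bulk RNA-seq of rice seedlings:
    class-code classification of assembled transcripts against a reference
    annotation, a five-stage lncRNA screening pipeline (class code, length,
    known-RNA similarity, coding-potential consensus, miRNA similarity,
    expression floor), differential expression under salt and hyperosmolarity
    stress with genotype-relatedness classification, weighted co-expression
    network analysis with module-trait correlation and hub calling,
    cis-regulatory target prediction by genomic window plus expression
    correlation, GO term enrichment, cross-species ortholog counting, and
    motif-architecture classification of a homolog family. Includes a
    deterministic synthetic-data generator that emulates the 24-sample
    genotype x tissue x treatment design with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
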