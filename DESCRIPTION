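Package: pirsig
Title: piRNA Signature Analysis for Small RNA Sequencing Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification and characterisation of disease-associated piRNA
    and piRNA-like small RNA signatures from small RNA sequencing data.
    Provides reference loading with element-of-origin annotation (SINE, LINE,
    LTR, genic), read-to-reference assignment allowing at most one mismatch,
    a self-contained negative-binomial Wald differential expression stage
    with covariates and Benjamini-Hochberg adjustment, element-of-origin
    enrichment against a genome-wide null, positional nucleotide composition
    profiles (5' uridine bias, cytosine enrichment), epigenetic-memory
    fractions across differentiation stages, direction-stratified
    cross-cohort overlaps, hierarchical clustering of top deregulated
    features, and a fully seeded synthetic-data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    MASS,
    mclust,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    jsonlite,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
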