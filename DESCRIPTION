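Package: lncscape
Title: Identification and Characterization of Long Noncoding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for building a genome-wide long noncoding RNA
    (lncRNA) catalogue from assembled transcript models and a reference
    annotation, modelled on the workflows used for insect lncRNA
    landscapes. Transcripts are classified by genomic context
    (intergenic, intronic, antisense) against the reference, passed
    through a multi-criterion coding-potential filter cascade (length,
    exon count, ORF size, external coding evidence, expression level),
    and the surviving lncRNA set is characterized by tissue-specificity
    scoring (Jensen-Shannon and tau indices), transposable-element
    overlap enrichment, cross-species sequence conservation and
    synteny-based homology families, and expression correlation with
    neighbouring protein-coding genes, including hypergeometric GO
    enrichment of partner genes. A deterministic synthetic-data
    generator plants ground truth for every pipeline stage, so each
    component is testable end to end.
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
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
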