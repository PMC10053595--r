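Package: aseditr
Title: Allele-Specific Expression, RNA-Editing and lncRNA Triage from RNA-Seq Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based post-processing of transcriptome variant calls from a
    two-group RNA-Seq design: a multi-stage single-nucleotide-variant filter
    cascade (quality, genomic-context, proximity and prevalence rules), a
    binomial likelihood-ratio test for differential allelic expression with
    Benjamini-Hochberg correction and chi-square allelic-balance
    classification, codon-aware variant consequence annotation, a canonical
    A-to-I / C-to-U RNA-editing candidate branch with SINE-overlap and
    editing-efficiency rules, a native perfect-microsatellite (SSR) scanner,
    a consensus long-noncoding-RNA identification cascade, and cis/trans
    lncRNA-gene interaction triage from co-expression and binding evidence.
    Includes a seeded synthetic-data generator with a complete planted-truth
    ledger so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
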