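Package: fracseq
Title: Discovery of Nuclear-Enriched Disease-Associated lncRNAs from
    Fractionation RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering nuclear-enriched,
    tumor-associated long noncoding RNAs (lncRNAs) from subcellular
    fractionation-then-sequencing experiments. Provides transcript catalog
    comparison by intron chain (transfrag-style class codes, assembly
    intersection and per-condition assembly support), a lncRNA filter
    cascade with dual coding-potential consensus, consensus differential
    expression across methods with a built-in nonparametric test,
    housekeeping-calibrated classification of genes as nuclear- or
    cytoplasmic-enriched from paired cytoplasmic/nuclear FPKM profiles,
    candidate characterization (promoter H3K4me3 marks, preimplantation
    embryo expression, Kaplan-Meier/log-rank survival screening),
    co-expression partner selection, and a seeded synthetic-data generator
    that emulates the statistical structure of such studies so the whole
    pipeline is testable end-to-end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    survival,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
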