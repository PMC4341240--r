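Package: taprootmir
Title: Small RNA-Seq miRNA Discovery and Differential Expression for
    Staged Taproot Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a staged small RNA-seq miRNA
    pipeline for plant storage-root development: raw FASTQ cleaning with
    per-category removal accounting, collapsing to unique small-RNA tags,
    hierarchical annotation against non-coding RNA and mature miRNA
    catalogs, novel miRNA prediction from hairpin secondary structure with
    a nearest-neighbor minimum-free-energy folder, reads-per-million
    normalization with exact-test (Audic-Claverie) differential-expression
    screening across three developmental stages, plant miRNA target
    scanning with a complementarity expectation score, expression-pattern
    clustering, and 2^-ddCt RT-qPCR relative quantification. Ships a
    synthetic-data generator that plants known miRNAs, hairpin loci, ncRNA
    contaminants and library-preparation artifacts with fully known truth,
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
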