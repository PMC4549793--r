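Package: msicall
Title: Microsatellite Instability Classification from Somatic Mutation Catalogs
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines tumor microsatellite instability (MSI) status from
    catalogs of somatic single-nucleotide substitutions and microindels.
    Computes per-megabase mutation-rate variables over a simple-repeat
    annotation (homopolymer runs scanned from a reference sequence plus
    UCSC-style tandem-repeat tables), classifies tumors as MSI-H or
    non-MSI-H with a packaged single-threshold decision tree (exome and
    whole-genome variants), flags possible POLE-deficient ultra-hypermutated
    tumors, and supports retraining via gain-ratio decision-tree induction
    with stratified cross-validation. Includes evaluation utilities
    (one-sided Fisher exact test, ROC/AUC, concordance, capture-subset
    robustness experiments, repeat-density summaries) and a synthetic cohort
    generator that writes MAF, BED, FASTA and TSV fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
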