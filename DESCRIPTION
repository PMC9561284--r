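Package: m5cmap
Title: miCLIP Crosslink-Site Mapping and RNA Bisulfite Conversion
    Quantification for m5C Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Localizes NOP2/NSUN1-dependent 5-methylcytosine (m5C) on
    ribosomal and small non-coding RNA from two complementary sequencing
    assays. The miCLIP arm maps reverse-transcription stop sites from
    crosslink-truncated reads, normalizes IP coverage against a
    size-matched input (SMInput) library, and calls candidate crosslink
    sites with windowed Fisher/Benjamini-Hochberg enrichment tests. The
    bisulfite arm quantifies per-cytosine C-to-T conversion on targeted
    amplicons with a three-letter (C-collapsed) local aligner and compares
    conditions across biological replicates with Student's t-tests. A
    seeded synthetic-read generator emulates crosslink truncation,
    binding-window enrichment, UMI/adapter read structure and bisulfite
    chemistry, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
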