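Package: riboperon
Title: Characterizing Tandem-Repeat Ribosomal Operons from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the nuclear ribosomal DNA (nrDNA) tandem
    repeat of fungal genomes from short-read sequencing data. Estimates operon
    copy number from the ratio of nrDNA read depth to single-copy-locus depth,
    profiles per-site intragenomic variance across the ITS barcode region,
    detects intron presence or absence from assembled operons and from raw
    reads via junction-motif search, counts minimum intron gain/loss events on
    a phylogeny by Fitch and Dollo parsimony, and contrasts intragenomically
    polymorphic sites with species-diagnostic barcode positions. A fully
    ground-truthed simulator of tandem-repeat genomes and Illumina-style
    paired-end reads makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
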