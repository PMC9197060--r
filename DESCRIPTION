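Package: poreclone
Title: Finishing Pooled Large-Insert Clones with Ultra-Long Nanopore Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computational pipeline for finishing large-insert (BAC/fosmid)
    clone sequences from a single pooled nanopore run plus per-clone Illumina
    data. Pooled ultra-long reads are demultiplexed to clones by alignment
    against draft assemblies (no barcodes required), full-length reads that
    traverse the entire circular clone are identified by cloning-vector
    anchors and rotated to a canonical vector-first orientation, a per-clone
    consensus is polished with long reads and then corrected to the Illumina
    consensus, and near-identical internal repeats (amplicons) are resolved
    by partitioning reads on sequence family variants and polishing each
    repeat unit separately. A synthetic clone-pool simulator provides ground
    truth for every stage, and SAM alignments can be split into sub-alignments
    that respect the 65535 CIGAR-operation limit of the BAM format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
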