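Package: owlgenome
Title: Assembly Metrics, Two-Genome Divergence, and Light-Associated Gene
    Loss Screens for Owl Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the bespoke computations
    behind a draft owl genome analysis: genome-assembly continuity and
    composition statistics under explicit N-run contig-splitting
    conventions (Nx/Lx, length classes, gap statistics), estimation of
    within- and between-species per-nucleotide diversity and Hudson's
    fixation index from a two-individual variant table with the study's
    site filters, screening of candidate gene loci for inactivating
    mutations (start-codon loss, premature stops, frameshift indels,
    canonical splice-site disruption) plus gene-deletion inference from
    flanking-gene synteny, in-silico microsatellite mapping with PCR
    product-length and inter-locus distance inference, and seeded
    synthetic-data generators with exact ground truth so every analysis is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
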