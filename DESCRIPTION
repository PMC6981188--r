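Package: mmejquant
Title: Quantification of MMEJ-Mediated Mutation-Replacement Genome Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a dual-cut CRISPR-SaCas9 locus in which a pathogenic
    deletion is replaced by a donor sequence via microhomology-mediated end
    joining (MMEJ), classifies clone amplicon sequences into editing-outcome
    categories (Success, Deletion, cleavage-site indel, AAV integration,
    other indel, unedited), corrects observed Success rates for
    amplicon-length-dependent PCR detection bias via a mixture-series
    regression, and screens variant tables and split-read alignments for
    off-target events and vector integration junctions. Includes seeded
    synthetic-data generators for every input so the full pipeline can be
    exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
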