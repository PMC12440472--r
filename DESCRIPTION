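Package: admecov
Title: Pharmacogene Panel Coverage of Genotyping and Enrichment Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses how well genotyping arrays and target-enrichment
    designs cover a panel of pharmacogene (ADME) variants. Computes direct
    (physical) coverage of a variant list against platform manifests,
    linkage-disequilibrium-adjusted coverage via tag SNPs at a configurable
    r-squared threshold computed from phased haplotypes, and base-level
    coverage of capture-probe interval designs with a high/low (>= 90%)
    classification per target region. Ships the 34-variant
    CYP2C8/CYP2D6/CYP3A4/CYP3A5 core panel and its published platform
    coverage matrix as fixtures, and includes a block-LD haplotype
    simulator so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
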