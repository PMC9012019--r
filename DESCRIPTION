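Package: herdscan
Title: Population-Genomic Scans and Platform Concordance for Livestock SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for population genomics of low-coverage
    livestock genotype panels: concordance accounting between
    genotyping-by-sequencing and whole-genome-sequencing call sets, windowed
    nucleotide diversity and Weir-Cockerham/Hudson F_ST, the population branch
    statistic (PBS) selection scan, a site-frequency-spectrum composite
    likelihood ratio sweep scan, Patterson's D ('ABBA-BABA') introgression
    tests with block-jackknife standard errors, PCA and neighbour-joining
    structure inference, and empirical-outlier window-to-gene overlap
    accounting. Includes a seeded multi-population drift simulator with
    localized selective sweeps and a depth-aware sequencing-platform emulator
    so every stage is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    ape,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
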