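Package: bsmethyl
Title: Downstream Analysis of Whole-Genome Bisulfite Sequencing Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for the downstream analysis of whole-genome bisulfite
    sequencing (WGBS) data in sparsely methylated genomes such as insects.
    Classifies cytosines into CpG/CHG/CHH contexts on both strands, computes
    observed/expected context-depletion ratios from genome composition,
    stratifies methylation levels by context, strand and gene feature
    (exon/intron/genic/intergenic), performs replicate-aware differential
    methylation with a beta-binomial Wald test and area-statistic region
    calling, implements plate-based 5mC/5hmC and DNMT-activity quantification
    and Pfaffl relative expression, and ships a seeded bisulfite-methylome
    simulator with planted, recoverable parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
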