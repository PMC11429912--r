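Package: hapolish
Title: Phase-Aware Diploid Assembly Polishing and K-mer Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for polishing haplotype-resolved diploid genome
    assemblies with long-read alignments. Implements phase-aware reassignment
    of HiFi reads in long homozygous assembly regions using ultra-long read
    phasing evidence (variant-block edit-distance scoring), candidate-window
    detection and pileup-consensus polishing with VCF edit emission,
    class-specific genotype-quality filtering of proposed edits, edit
    application, and k-mer based quality-value assessment including
    fixed/induced/unchanged error k-mer accounting, GQ cutoff sweeps, error
    context stratification, and coding-sequence impact analysis. A seeded
    synthetic diploid genome and long-read simulator generates all inputs, so
    every component is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    withr,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
SystemRequirements: minimap2 (for the alignment steps of the end-to-end
    pipeline; individual components run without it)
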