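Package: fivep
Title: Co-Translational mRNA Decay Analysis from 5'P Degradome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 5'P degradome sequencing (5P-Seq) data for
    co-translational 5'-3' mRNA decay: UMI extraction and PCR-duplicate
    collapsing, per-transcript 5'P coverage, anchor-aligned metagene
    profiles and reading-frame histograms, 45-nt window loading ratios
    around the start and stop codons, and genotype comparison statistics
    (per-gene scores, cumulative distributions, Mann-Whitney subset shift
    tests). Also implements a label-free RNP mass-spectrometry enrichment
    funnel (top-3 and count/MW quantification, median normalization,
    replicate rules, t-tests, fold-change filters) and small calculators
    for pull-down qPCR enrichment, mRNA half-life, translation-efficiency
    ratios and polysome P/FM ratios. Ships simulators for degradome
    reads, peptide tables and assay time-courses with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    IRanges,
    S4Vectors,
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
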