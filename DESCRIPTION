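Package: mavatlas
Title: Variant-Effect Atlases Across Environments and Genetic Backgrounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interpreting multiplexed assay of variant
    effect (MAVE) atlases measured across environmental gradients and genetic
    backgrounds, modelled on a yeast-complementation TileSeq screen of human
    MTHFR across four folinate concentrations in wild-type and p.Ala222Val
    backgrounds. Provides enumeration and HGVS parsing of protein variant
    spaces; a seeded simulator of the full experiment (Poisson mutagenesis
    libraries, growth selection, paired-read sequencing counts, residue
    annotations, and a recessive clinical cohort); enrichment-based
    functionality scoring with mode-calibrated rescaling and regularized
    errors; weighted linear dose-response models with likelihood-ratio tests;
    genetic-interaction models against a polynomial double-mutant expectation,
    including suppressor detection; screening statistics (Welch, Mann-Whitney,
    Fisher) with FDR control; and clinical calibration of scores into
    log-likelihood ratios of pathogenicity with balanced precision-recall
    evaluation of diploid genotype models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
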