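Package: zwdc
Title: Dosage Compensation Analytics for ZW Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying histone-acetylation-mediated dosage compensation
    on the differentiated stratum of a ZW sex chromosome system: transcriptome
    based sex inference from expressed-SNP allelic balance, CUT&Tag-style
    coverage binning with female/male log2 fold-change summaries over
    evolutionary strata, dosage-compensation onset testing in embryos, bin-wise
    differential expression scans, aging-associated variability statistics, and
    sex-specific survival analysis (Kaplan-Meier and stratified log-rank).
    Includes a seeded synthetic ZW/ZZ data generator that emits every input the
    pipeline consumes, so all stages are testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
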