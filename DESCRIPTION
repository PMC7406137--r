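Package: lignosom
Title: Cross-Species Transcriptome and Secretome Integration with
    Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates bulk RNA-seq transcriptomes and LC-MS/MS secretomes
    from several related fungal species into one cross-species analysis of
    wood-decay enzyme co-regulation. Provides low-count masking,
    median-of-ratios size-factor normalization, empirical-Bayes
    location-scale batch adjustment, quantile normalization, hexagonal
    self-organizing map clustering of gene expression profiles,
    substrate-responsive node filtering, one-to-one ortholog conservation
    scoring, secretome overlay statistics, and a negative-binomial
    multi-omics simulator with planted ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    DESeq2,
    mclust,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
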