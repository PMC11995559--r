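Package: acripseq
Title: ac4C Epitranscriptome Analysis from acRIP-Seq with Proteome and
    Transcriptome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of N4-acetylcytidine (ac4C) RNA modification
    profiling by acetylated-RNA immunoprecipitation sequencing (acRIP-seq).
    Detects enriched windows against input controls with a Poisson scan,
    applies exon, fold-enrichment, IgG-calibration and replicate-consensus
    filters, computes per-mRNA fold enrichment and pseudocounted fold change,
    performs empirical-Bayes moderated differential testing with
    exclusive-detection rules, quantifies matched RNA-seq (TPM) and label-free
    proteomics (FOT) layers, and integrates the three omics layers into Venn
    and cross-classification summaries. Includes a seeded synthetic-data
    generator with a planted ground truth for validation.
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
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    limma,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
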