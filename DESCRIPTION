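Package: pleioqtl
Title: Multi-Trait GWAS, eQTL Mapping and Summary-Based Mendelian
    Randomisation for Fertility Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for dissecting pleiotropic loci
    behind correlated quantitative traits, built around cattle fertility
    genetics. Implements linear mixed-model association with a genomic
    relationship matrix, a conditional multi-trait chi-squared scan with
    stepwise LD-aware selection of putative causal variants, a closed-form
    false discovery rate estimator, hierarchical cis/trans eQTL mapping with
    two-step Bonferroni correction, summary-data-based Mendelian
    randomisation, regulatory-region enrichment, and a synthetic-data
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
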