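Package: lincnet
Title: Discovery, Differential Expression and ceRNA Network Analysis of
    Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for characterising long noncoding
    RNAs (lncRNAs) from an assembled transcriptome: classification of
    assembled transcripts against a reference annotation (antisense,
    intergenic, intronic), retention filtering, a two-classifier
    coding-potential gate (a four-feature logistic scorer using ORF size,
    ORF coverage, the Fickett TESTCODE statistic and hexamer usage bias,
    plus a k-mer large-margin classifier), catalog merging and
    nearest-gene nomenclature, negative-binomial differential expression
    with a two-test consensus rule, cis/trans co-expression analysis, and
    competing endogenous RNA (ceRNA) network construction from shared
    miRNA seed sites.  Every pipeline input can be simulated with planted
    ground truth, so each stage is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
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
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
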