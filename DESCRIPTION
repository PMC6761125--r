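Package: pausepoint
Title: RNA Polymerase II 3' Pausing and Transcriptional Interference at Tandem Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying 3' RNA polymerase II pausing and
    transcriptional interference between closely spaced tandem genes from
    ChIP-seq coverage and RNA-seq differential-expression tables. Implements
    per-gene 3' pausing indexes with paired group comparisons, winsorized
    metagene profiles with Gaussian confidence intervals, TES-shift estimation
    between conditions, neighbor-context annotation of gene pairs (orientation,
    intergenic distance), peak-to-feature annotation with fixed category
    precedence, negative-binomial greylist construction from control tracks,
    nucleosome-free-region calling, gene-loop enrichment, and the
    threshold-based selection procedures and nonparametric tests used to detect
    light-modulated transcriptional interference. Ships a fully parameterized
    synthetic-data generator with ground-truth bookkeeping so every analysis
    stage can be validated against planted truth.
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
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
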