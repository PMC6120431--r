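Package: tidalplast
Title: Transcriptomic Plasticity Versus Evolved Divergence in Tidal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the relationship between evolved
    expression divergence and expression plasticity in a two-site, two-tidal-level,
    time-course RNA-seq design. Provides negative-binomial differential expression
    with Benjamini-Hochberg correction, classification of genes into evolutionarily
    divergent, concordantly plastic and adaptive plastic sets, sign-concordance and
    Spearman rank statistics with a label-permutation null, discriminant-axis
    (DAPC-style) quantification of genome-wide expression shifts with Bayesian
    linear-mixed-model inference, increased-plasticity dynamics, Livak 2^-ddCt
    relative quantification for qPCR tables, and a negative-binomial count
    simulator with planted divergence and plasticity effects for validation.
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
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
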