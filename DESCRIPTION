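Package: rhythmecon
Title: Costs, Noise and Selection on Rhythmic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking 24-hour (nycthemeral) rhythmicity of
    gene expression to the energetic cost of protein expression,
    tissue-specific expression, single-cell expression noise, and purifying
    selection. Provides cosinor and robust-permutation rhythm detectors,
    empirical Brown's method for combining dependent p-values, amino-acid
    biosynthetic cost tables and per-protein expression costs, the Yanai
    tissue-specificity index tau, a delta statistic contrasting expression
    between rhythmic and non-rhythmic tissues, the mean-decorrelated
    single-cell noise statistic F*, and expression-controlled dN/dS
    comparisons. A synthetic-data generator with planted effects makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    Biostrings,
    dplyr,
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
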