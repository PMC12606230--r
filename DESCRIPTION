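Package: memmeta
Title: Metacognitive Sensitivity Across Iconic and Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for partial-report experiments
    comparing metacognitive sensitivity between iconic and working memory.
    Provides a generative observer model with per-condition 1-up/1-down
    staircases and ordered-probit confidence, the pre-registered trial and
    subject exclusion rules, type-2 ROC / AUROC-2 metacognitive sensitivity,
    paired-t and TOST equivalence inference, cumulative-probit mixed
    regression (adaptive Gauss-Hermite and Laplace estimation), analytic and
    simulation-based power analysis, and an end-to-end study pipeline with
    an explicit outcome-interpretation rule set.
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
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
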