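Package: mgmr
Title: Population-Coupled Estimation of RNA-Seq Expression from Multireads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-sample transcript or gene expression proportions
    from ambiguously mapped RNA-seq reads (multireads). Samples drawn from a
    common population are coupled through a shared Dirichlet prior whose
    hyperparameters are learned by a digamma fixed-point iteration, alternating
    with per-sample EM updates of the expression proportions (the MGMR
    procedure). Includes a read simulator for paralogous gene families with
    per-base sequencing errors, exhaustive mismatch-bounded read mapping,
    estimate-versus-truth error measures (relative error, chi-squared,
    Kullback-Leibler divergence), and a command-line pipeline tying the
    pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
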