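Package: seedhmm
Title: Multilevel Hidden Markov Models for Weed Seed-Bank Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates seed-bank survival, germination, and external
    colonization probabilities of weed species from yearly above-ground
    presence-absence surveys, using a three-state hidden Markov model whose
    demographic parameters vary with plot-level environmental and management
    covariates through species-level random slopes, and whose
    management-practice slopes are regressed on seed mass. Includes an exact
    forward-algorithm likelihood with an enumeration oracle, an adaptive
    Metropolis-within-Gibbs sampler, a synthetic survey generator emulating a
    multi-year vineyard flora monitoring design, and posterior reporting
    (credible intervals, split-chain Rhat, effective sample size, multilevel
    explained variance, and slope-versus-seed-mass tables).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
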