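Package: gustate
Title: Illness-Modulated Gustatory Cortical Coding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis battery for rodent gustatory cortex recordings around
    illness induction: Bayesian single change-point detection on local field
    potential (LFP) mu-band (7-12 Hz) power, rearing-based sickness-onset
    estimation with sigmoid fits, a change-point-coupling null simulation,
    single-neuron taste responsiveness classification, leave-one-out linear
    discriminant ensemble taste decoding, moving-window palatability rank
    correlation and a pure palatability index, and Gaussian-mixture clustering
    of held-unit response-difference vectors. A built-in synthetic-data
    generator with planted ground truth makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
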