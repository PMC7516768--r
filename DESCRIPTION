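Package: stablesize
Title: Stable-Size Preferential Attachment and Maximum-Entropy Size
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulators and estimators for preferential-attachment
    processes whose total size is stationary: an urn-and-ball process in
    which balls are deleted and urns turn over, and its network analogue
    with edge rewiring and node turnover.  Includes the maximum-entropy
    machinery that predicts the stationary size or degree distribution
    P(n) = K n^-(alpha+1) exp(-beta n) from the mean size and the
    geometric-mean (entropy) constraint, discrete maximum-likelihood
    fitting of the power law with exponential cutoff, fluctuation-scaling
    (Taylor-law) exponent estimation, an exact single-urn master-equation
    oracle, individual and aggregate growth-rate distributions with their
    upper-incomplete-Gamma closed form, and reference models
    (Maxwell-Boltzmann, Yule, multiplicative noise) that validate the
    entropy argument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
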