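Package: serialbias
Title: Dissociating Attractive and Repulsive Sequential Biases in Perceptual Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-to-trial history effects in circular
    estimation tasks (for example motion-direction report). Generates
    random-walk stimulus sequences and model-based responses, removes
    idiosyncratic cardinal-axis biases by Gaussian-process regression,
    fits derivative-of-Gaussian bias-curve mixtures with a hierarchical
    Bayesian Metropolis-Hastings sampler, compares models by AIC with
    BCa bootstrap intervals, builds marginal, joint and conditional bias
    maps, and simulates an encoder-decoder ideal observer with Poisson
    population coding, rapid gain adaptation and recursive Bayesian
    decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    readr,
    jsonlite,
    generics,
    boot,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
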