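Package: sphmm
Title: Sticky Poisson Hidden Markov Models for Neural Spike-Train Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits Poisson hidden Markov models to ensembles of simultaneously
    recorded spike trains and segments trials into sequences of hidden
    firing-rate states. Implements the vanilla Poisson-HMM, a "sticky" variant
    that enforces a hard lower bound on self-transition probabilities via a
    snapshot-reset-shuffle training loop, a maximum-a-posteriori variant with a
    Dirichlet prior on the transition rows, and a categorical (Multinoulli)
    benchmark model. Includes multi-trial Baum-Welch training, posterior and
    Viterbi decoding with an undecided-bin rule, model selection over the
    number of states by cross-validation, BIC and AIC, a decoded-squared-error
    model-comparison index with a shuffled null, Hungarian state matching,
    Markov-modulated Poisson process and clustered leaky integrate-and-fire
    network simulators, and circular/swap shuffle controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
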