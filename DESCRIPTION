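Package: enhancerkit
Title: Enhancer and Enhancer-Strength Identification from DNA Words
Version: 0.1.0
Authors@R:
    person("enhancerkit", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for identifying 200-bp enhancer fragments and grading
    their strength from sequence alone, treating DNA as a language. It
    provides deterministic n-gram word segmentation and a statistics-based
    segmenter (byte-pair-encoding seeding, EM-fitted unigram word
    probabilities, loss-ranked pruning and Viterbi decoding), skip-gram
    word embeddings trained with negative sampling, a sequence generative
    adversarial network for data augmentation of discrete DNA token
    sequences (policy-gradient generator with Monte-Carlo rollout rewards),
    a multi-width convolutional text classifier arranged as a two-layer
    predictor (enhancer versus non-enhancer, then strong versus weak), and
    leakage-safe cross-validation with accuracy, sensitivity, specificity
    and Matthews-correlation metrics. A synthetic benchmark-shaped data
    generator makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
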