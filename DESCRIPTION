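Package: localsampler
Title: Local Sampling Models of Human Random Sequence Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates and compares generative models of human random
    sequence generation: independent sampling, a schema-based generator,
    and six Markov chain Monte Carlo samplers built by adding multiple
    tempered chains, gradient-based (Hamiltonian) proposals, and partial
    momentum recycling to a Metropolis-Hastings base. Provides the
    randomness indices used to characterise such sequences (repetitions,
    adjacencies, turning points, central turning points, step distances,
    and a distributional Shape statistic), permutation ("reshuffle") null
    expectations, and approximate Bayesian computation with random forests
    for model comparison, including recursive posterior construction,
    class- and feature-level Bayes factors, and model-recovery evaluation.
    A synthetic-cohort generator emulates the structure of random
    generation experiments (height production and spatial syllable
    layouts) so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
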