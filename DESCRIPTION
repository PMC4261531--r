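Package: rjtraits
Title: Reversible-Jump MCMC for Correlated Binary Trait Evolution on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian comparative analysis of binary morphological
    characters on a posterior sample of phylogenetic trees.  Implements
    continuous-time Markov models for single characters (2 states) and
    character pairs (4 states, with dependent 8-rate and independent
    4-rate parameterisations), exact pruning likelihoods, and a
    reversible-jump MCMC sampler over rate-class partitions that
    includes a structural-zero bin.  Provides marginal ancestral-state
    reconstruction at designated clades via the MRCA approach,
    harmonic-mean Bayes-factor tests of dependent evolution for all
    character pairs, Z-score summaries of rate restriction, and
    assembly of tiered contingency networks describing the temporal
    order in which character-state changes accumulated.  Includes a
    synthetic-data generator (pure-birth trees, jittered tree samples,
    planted dependencies and planted contingency chains) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
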