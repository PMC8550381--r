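Package: traitsse
Title: Trait-Dependent Diversification Analysis on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A comparative-phylogenetics pipeline for testing whether discrete
    traits are associated with lineage diversification. Provides gap coding of
    continuous traits, continuous-time Markov (Mk) models with equal-rates,
    symmetric, all-rates-different and ordered ("constrained") transition
    structures, marginal ancestral state reconstruction, stochastic character
    mapping with transition counting, phylogenetic signal statistics
    (Blomberg's K, Pagel's lambda for continuous and discrete traits,
    simulation-based phylogenetic ANOVA), lineage-through-time diagnostics
    with the gamma statistic and the Monte Carlo constant-rates (MCCR) test,
    and a multistate hidden-state speciation-extinction (SSE) engine with an
    eight-model set, multi-start maximum likelihood, AIC ranking, Akaike-weight
    model averaging and marginal reconstruction. Ships state-dependent
    birth-death, Mk and Brownian-motion simulators so every stage is testable
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
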