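Package: vertbrain
Title: Phylogenetic Comparative Analysis of Vertebrate Brain-Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analyses of encephalization across
    vertebrate classes: harmonization of heterogeneous newborn- and
    brain-size measurements into common mass units with allometric
    quality-control filters, assembly of a dated vertebrate supertree by
    grafting class-level chronograms at calibrated divergence ages,
    phylogenetic generalized least squares with maximum-likelihood or
    REML Pagel's lambda, a Gibbs-sampled Bayesian phylogenetic mixed
    model (animal model) with parameter-expanded variance priors, and
    phylogenetic path analysis over candidate causal graphs using
    d-separation tests, Fisher's C and CICc model averaging. Includes a
    trait-evolution simulator for end-to-end validation and parameter
    recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    coda,
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
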