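Package: carapace
Title: Diversification, Trait Jumps, and Extinction Risk on Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end comparative pipeline for macroevolution and
    conservation prioritization on dated ultrametric phylogenies, motivated by
    the biology of turtles and crocodilians. Implements episodic birth-death
    likelihoods with explicit mass-extinction events and a CoMET-style
    reversible-jump MCMC with Bayes-factor event detection; a Levy
    jump-diffusion (Brownian motion plus compound-Poisson jumps) model of
    body-size evolution with per-branch jump posteriors, an alpha peak-finder
    and a likelihood-ratio test against Brownian motion; fair-proportion
    evolutionary distinctiveness (ED) and EDGE scoring over tree posteriors;
    an ensemble (phylogenetic GLS, random forest, neural network) imputation
    of ordinal IUCN threat status with phylogenetic and spatial eigenvector
    covariates; gridded richness summaries; and a synthetic-data module that
    generates trees, traits, predictors, statuses, and ranges with known
    ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    coda,
    randomForest,
    nnet,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    deSolve,
    mvtnorm
Config/testthat/edition: 3
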