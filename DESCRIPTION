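Package: echinoasr
Title: Bayesian Ancestral State Reconstruction of Spatial Gene Expression
    on Fossil-Calibrated Echinoderm Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs ancestral states of discrete spatial
    gene-expression characters (alx1, erg, ets1, tbrain, vegfr) on
    time-calibrated echinoderm phylogenies under continuous-time Markov
    (Mk) models. Provides Metropolis-Hastings sampling of transition
    rates integrated over a sample of chronograms, exact per-iteration
    marginal state probabilities at named ancestral nodes, stepping-stone
    estimation of marginal likelihoods, Bayes-factor comparison of rate
    models and node-fixed hypotheses, a calibration-constrained
    chronogram sampler driven by seven echinoderm fossil calibrations,
    simulation of discrete characters on trees, and prior/model/taxon
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    ape,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
NeedsCompilation: yes
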