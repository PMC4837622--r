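Package: pedliab
Title: Threshold-Linear Animal Models for Ordinal and Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation of genetic parameters for an ordinal trait
    analysed jointly with quantitative traits in pedigreed populations.
    Implements pedigree handling with the additive relationship matrix and
    its sparse inverse (Henderson's rules with inbreeding by the
    Meuwissen-Luo algorithm), a Gibbs sampler for bivariate threshold-linear
    animal models with a latent liability for the ordinal trait, posterior
    summaries of heritabilities and genetic correlations with the
    Dempster-Lerner scale transformation and Heidelberger-Welch convergence
    diagnostics, phenotypic characterization tools (incidence tables,
    chi-squared comparisons, least-squares means with Tukey-Kramer
    adjustment), and a synthetic-data generator emulating a two-line
    divergent truncation-selection breeding scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
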