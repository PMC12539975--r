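Package: srmnet
Title: Bayesian Multiplex Social Relations Models for Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian inference for multiplex (multi-layer)
    directed social networks using the social relations model (SRM). Supports
    Bernoulli, Binomial (with exposure), Poisson, and Gaussian outcome layers;
    estimates within- and between-layer generalized and dyadic reciprocity
    through correlated sender/receiver and dyad-level random effects, with the
    block-structured dyadic correlation matrix enforced by a soft penalty;
    block (assortativity) intercept offsets and focal, target, and dyadic
    covariate regressions. Inference uses a built-in No-U-Turn Hamiltonian
    Monte Carlo sampler over an analytically differentiated joint log density.
    Post-processing includes posterior summaries with highest-posterior-density
    intervals, three- and four-way variance partitions, variance-adjusted
    dyadic correlations, reciprocity matrices, posterior block contrasts,
    posterior network metrics, and a Frobenius-norm parameter-recovery
    validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
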