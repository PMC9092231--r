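Package: crcsize
Title: Population Size Estimation from Multi-Source Capture-Recapture Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for closed-population size estimation from two or more
    encounter events (lists), as used in key-population HIV surveillance.
    Provides data containers and validation for capture-history,
    individual-level and aggregated event-count formats with exact conversion
    between them; classical log-linear (Poisson regression) estimators
    (M0, Mt, Mh, Mth) with Normal, Poisson, Gamma and Darroch heterogeneity
    corrections and the Chao lower bound; pairwise Chapman diagnostics;
    Bayesian model averaging over decomposable graphical models of list
    dependence with noninformative or truncated log-normal priors on
    population size; a Bayesian nonparametric latent-class (stick-breaking
    Dirichlet process) Gibbs sampler with MCMC diagnostics; and a
    simulation-based precision calculator for study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, pracma, yaml
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'decomposable.R'
    'bma.R'
    'design-matrix.R'
    'loglinear.R'
    'chao.R'
    'lcmcr.R'
    'diagnostics.R'
    'normal-mixing.R'
    'samplesize.R'
    'report.R'
    'cli.R'
    'crcsize-package.R'
    'descriptives.R'
    'event-counts.R'
    'history-table.R'
    'io.R'
    'pairwise.R'
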