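Package: bcnma
Title: Bayesian Component Network Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian component network meta-analysis (CNMA) for networks of
    complex interventions built from combinations of elementary components.
    Fits additive models, models with two-way component interactions selected
    by stochastic search variable selection (spike-and-slab) or shrunk by a
    Bayesian LASSO, and one-stage joint models combining aggregate data with
    individual participant data, including component-covariate interactions
    and patient-specific prediction of relative treatment effects. Includes
    design/estimability diagnostics for component networks, a synthetic-data
    generator with known truth for parameter-recovery checks, pooling of
    posterior draws across multiply imputed datasets, and a command-line
    interface. MCMC sampling uses JAGS via the rjags package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
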