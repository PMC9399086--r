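Package: socialpt
Title: Hierarchical Bayesian Prospect Theory for Social Risky Choice
Version: 0.1.0
Authors@R:
    person("socialpt", "maintainers", email = "socialpt@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how making risky monetary choices for or with
    another person changes the component processes of decision-making under
    risk. Implements a prospect-theory valuation model (risk attitude rho,
    loss aversion lambda, softmax consistency mu) with additive social
    modulation terms on the unconstrained log scale, a generator for the
    mixed/gain-only gamble choice set and three-condition (self/other/shared)
    session structure, a synthetic-cohort simulator with trait covariates,
    hierarchical Bayesian estimation of three model variants by adaptive
    Markov chain Monte Carlo, highest-density-interval and WAIC inference,
    parameter-recovery reports, implied per-condition parameter tables, and
    individual-difference correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
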