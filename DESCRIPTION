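Package: tojflow
Title: Simulation and Hierarchical Analysis of Temporal Order Judgement Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing repeated-measures temporal
    order judgement (TOJ) experiments with attentional cueing. Provides a
    generative observer model and 1-up-3-down adaptive staircase simulator,
    logistic psychometric-function fitting with just-noticeable-difference
    (JND) and point-of-subjective-simultaneity (PSS) estimation, scoring of
    the 26-item Activity Flow State Scale (AFSS) with Cronbach's alpha,
    median/MAD outlier screening, and hierarchical linear models of
    flow-moderated pre-to-post change in temporal and spatial processing,
    including a Bayesian (MCMC) counterpart with leave-one-out predictive
    model comparison. A pipeline orchestrator runs the full chain from
    simulated (or deposited) trial data to coefficient tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    rjags,
    coda,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
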