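Package: tdcmediate
Title: Causal Mediation for Longitudinal Mediators with an Ordinal
    Treatment-Dependent Confounder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian causal mediation analysis for randomized intervention
    studies with a longitudinal continuous mediator, a restricted
    time-to-event outcome, and an ordinal treatment-dependent confounder.
    Fits a joint model combining a natural-cubic-spline linear mixed model
    for the latent mediator trajectory with a piecewise-constant
    proportional-hazards survival model sharing a frailty random intercept,
    and a Bayesian multinomial-logit model for the confounder. Natural
    direct and indirect effects on the restricted mean survival time are
    identified under monotonicity of the treatment effect on the confounder
    up to stratum-specific sensitivity parameters, with feasibility
    diagnostics, step-monotonicity, and partial-identification bounds
    without monotonicity. Includes a synthetic-data generator with full
    counterfactual bookkeeping and Monte Carlo oracle effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    survival,
    boot,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
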