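Package: weanmark
Title: Multistate Hidden Markov Mark-Recapture Models for Age at Weaning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate age-specific weaning probabilities of pinnipeds
    from resighting data using multistate Cormack-Jolly-Seber models with
    imperfect state detection, formulated as hidden Markov models. Includes an
    individual-based simulator of encounter records, robust-design capture
    history encoding with a number-of-sightings covariate, maximum-likelihood
    fitting with formula-based design matrices and link functions, AIC model
    weights, derived cumulative weaning proportions with multivariate-normal
    parametric bootstrap confidence intervals, neonatal body mass adjustment
    via linear model selection, B-spline covariate bases, and
    errors-in-variables linear regression for comparing derived life-history
    parameters across rookeries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tools,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
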