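Package: nlebias
Title: Number Line Estimation Bias Analysis and the Cyclical Power Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing bounded (0-100) number line estimation
    experiments across language groups: touch-coordinate preprocessing with
    exclusion rules and line-direction inference, positioning-bias and
    response-time summaries, intra-decade regression slopes, inverted-pair
    and decade-boundary analyses, mixed ANOVA with generalized eta-squared,
    and a modified one-/two-cycle cyclical power model with a unit-digit
    weight and a language modifier, fitted by nonlinear least squares.
    Includes a synthetic-cohort generator that emits raw touch coordinates
    under the quasi-randomized design constraints of the task, so the whole
    pipeline can be exercised and validated without behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
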