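# nlebias

Analysis toolkit for bounded (0–100) **number line estimation (NLE)**
experiments across native-language groups, built for studying two
signatures of two-digit number processing:

* the **left-digit effect** — the decade digit dominates perceived
  magnitude, compressing placings within decades and exaggerating
  decade boundaries;
* the **inversion effect** — languages that speak the unit before the
  decade (German "one-and-ninety" for 91) are hypothesised to give the
  unit digit extra weight.

The package covers the whole pipeline: raw touch-coordinate
preprocessing (exclusion rules, line-direction inference, conversion to
placing positions), positioning-bias and response-time summaries, mixed
ANOVA with generalized eta squared and Tukey-adjusted marginal-means
contrasts, intra-decade regression slopes, inverted-pair and
teen/twenty analyses, decade difference scores, and — at its core — the
**modified cyclical power model** with a language modifier. For a target
split into decade part $x_d$ and unit digit $x_u$, with transformed
magnitude $s = x_d + x_u^{\,\delta + \lambda L}$,

$$y = \frac{(s - LB)^{\beta}}{(s - LB)^{\beta} + (UB - s)^{\beta}}\,(UB - LB) + LB,$$

where $\beta > 0$ is the curvature around the segment anchors (two-cycle:
$[0,50]$ and $[50,100]$; one-cycle: $[0,100]$), $\delta$ is the
unit-digit weight ($\delta < 1$ = left-digit compression), and
$\lambda$ shifts $\delta$ for the comparison language ($L = 1$) relative
to the reference ($L = 0$). The model is fitted by nonlinear least
squares on median placing positions per language and target (> 20), and
$\lambda \ne 0$ is the language-specificity result.

A synthetic-cohort generator reproduces the study conditions — 50
printed targets × 4 repetitions × 2 line orientations per participant,
quasi-randomized under the task's adjacency constraints, timeouts
repeated at block end, responses emitted as raw pixels — so every stage
is testable end to end without behavioural data.

## Worked example

Simulate the default three-language cohort, preprocess it, and run the
slope analysis and the all-language model fit:

```r
library(nlebias)

cohort <- make_cohort(default_cohort_specs(), seed = 42)
data   <- preprocess_trials(cohort$trials)
data
#> Preprocessed number line estimation data
#>   95977 trials, 234 participants, languages: English, German, Mandarin
#>   excluded: 973 (off_line_axis 0, off_line_perpendicular 0, timeout 973)

cmp <- compare_slope_groups(participant_mean_slopes(decade_slopes(data)))
cmp$groups
#>   language      mean         sd  n
#> 1  English 0.6261429 0.06660321 80
#> 2   German 0.7024170 0.06263374 78
#> 3 Mandarin 0.3086544 0.07077882 76

fit <- fit_power_model(prepare_medians(data), reference = "English")
summary(fit)
#> Modified two-cycle power model (reference: English)
#>
#>                  Estimate Std. Error t value Pr(>|t|)
#> beta             0.896742   0.001807  496.24   <2e-16 ***
#> delta            0.824534   0.003643  226.32   <2e-16 ***
#> lambda_German    0.050464   0.004871   10.36   <2e-16 ***
#> lambda_Mandarin -0.236188   0.006835  -34.56   <2e-16 ***
#>
#> Residual SE 0.1725 on 125 df; n = 129; BIC = -437.97
```

Reading the output: mean intra-decade slopes order German > English >
Mandarin — the inversion-effect signature (steeper slopes = more unit
influence). The model fit recovers the generating parameters: a shared
curvature β ≈ 0.90, an English unit weight δ ≈ 0.82 (left-digit
compression), a slightly positive German modifier and a strongly
negative Mandarin modifier (λ ≈ −0.24), i.e. Mandarin speakers weight
the unit digit least. Group test statistics on synthetic cohorts are
much larger than in behavioural data because the generator has no
between-participant heterogeneity; see the methods vignette
(`vignettes/number-line-estimation.Rmd`).

A YAML-configured end-to-end run (simulation → preprocessing → all
analyses → CSVs and a markdown report) is available through
`validate_config()` / `run_pipeline()`.

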