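---
title: "Methods: number line estimation bias and the cyclical power model"
author: "nlebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: number line estimation bias and the cyclical power model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlebias)
```

## The task and the two effects

In a bounded number line estimation (NLE) task, participants see a
two-digit Arabic numeral and touch the point on a 0--100 line where it
belongs. Two systematic distortions of two-digit placings motivate this
package:

* the **left-digit effect** — the decade digit dominates the perceived
  magnitude, so within a decade the placings are compressed (29 is
  placed much closer to 21 than arithmetic warrants), and decade
  boundaries are exaggerated;
* the **inversion effect** — in languages whose spoken two-digit
  numbers name the unit before the decade (German
  *ein-und-neunzig*, "one-and-ninety"), the unit digit is
  hypothesised to carry extra weight, counteracting the left-digit
  compression.

The package implements the full analysis pipeline for a
cross-linguistic design with English (teens inverted, rest not), German
(fully inverting) and Mandarin (fully non-inverting) speakers, plus a
synthetic-cohort generator so every stage can be validated without
behavioural data.

## Preprocessing

Touches are recorded as pixel coordinates on a 1000-px line
(axis coordinate $-500 \dots +500$; the perpendicular coordinate is
fixed). The rules, in order:

1. **Exclusions.** A response is dropped when its axis coordinate lies
   beyond the line, when its perpendicular deviation exceeds 150 px
   (strict inequality: 150 px is retained), or when the 2500-ms
   response window elapsed (timeouts carry no coordinates). Exclusion
   fractions are reported against all recorded touch responses;
   timeouts against all presentations. The rules are idempotent.
2. **Direction inference.** Participants choose freely which end of the
   line is "small", so the direction is recovered per participant and
   orientation as the sign of the correlation between target and axis
   coordinate. A sliding-window correlation (window 25 trials) flags
   direction switchers: a window with $r > 0.5$ and another with
   $r < -0.5$. The window covers half a repetition cycle of the
   50-target set, long enough for $|r|$ near 1 in compliant responders
   and short enough to localise a mid-block switch; switchers are
   removed, as their converted positions would mix two reference
   frames.
3. **Conversion.** Retained touches map affinely to $[0, 100]$;
   descending lines are numerically turned around
   ($y \mapsto 100 - y$), so smaller outcomes always mean "towards the
   small end".

Training trials (targets 70, 30, 50 before each orientation block) are
preprocessed but flagged and excluded from every analysis.

## Bias metrics and group inference

The *positioning bias* of a trial is placing position minus target; the
*absolute positioning bias* is its absolute value (equivalent to
percent absolute error on a 0--100 line). Trial-level biases are always
averaged within participant (per line orientation) before any group
statistic — the group tests are participant-level throughout.

Group structure is assessed with a mixed two-way ANOVA (between:
mother tongue; within: line orientation) via `mixed_anova()`. With a
two-level within factor, sphericity holds trivially
(Greenhouse–Geisser $\varepsilon = 1$), so no correction is applied.
Effect sizes are generalized eta squared
($SS_\text{effect} / (SS_\text{effect} + \sum SS_\text{error})$,
both error strata in the denominator). Its 90% CI is obtained from the
noncentral-$F$ pivot (Steiger-type limits on the noncentrality
parameter), rescaled from the partial-eta to the generalized-eta scale
and clamped to contain the point estimate; the exact interval
construction for generalized eta squared is not settled in the
literature, and this choice is recorded as an assumption. Follow-up
pairwise language contrasts use estimated marginal means with Tukey
adjustment (package `emmeans`).

All t tests report Cohen's $d$: pooled-SD for independent groups,
SD-of-differences for paired and one-sample tests. Welch corrections
(fractional df) are used for independent comparisons. Near-constant
inputs degrade gracefully to the limiting test result instead of
erroring, flagged as degenerate.

## Inversion-effect measures

* **Inverted-pair distances** (`inverted_pair_distance()`): for the 17
  digit-reversal pairs with both members above 20 (23--32, ...,
  89--98), the absolute distance between the pair members' mean
  placings, averaged over pairs, per participant. A veridical responder
  scores exactly $477/17 \approx 28.06$. Stronger unit weighting pulls
  reversal pairs together, hence the one-tailed German < English test.
  This measure is confounded by any global (de)compression of the
  line, which is why the slope analysis below is the more sensitive
  operationalisation.
* **Intra-decade slopes** (`decade_slopes()`): OLS slope of placing
  position on target, per participant and decade above the teens, both
  orientations pooled, at the trial level (with a balanced design this
  equals the regression on per-target means). Slope 1 is veridical, 0
  is pure left-digit responding. Per-participant means over decades
  feed Welch tests: German > English and German > Mandarin one-tailed,
  English vs Mandarin two-tailed.
* **Teen/twenty comparison** (`teen_twenty_bias()`): per participant,
  mean bias over 13--19 versus the unit-matched 23--29; one-tailed
  paired t per language plus one-sample tests of each decade mean
  against zero. English inverts only the teens, so a relative teen
  overestimation is the item-level inversion signature.
* **Decade difference scores** (`decade_difference_scores()`): for
  boundary pairs with true distance 2 present in the stimulus set
  (19/21, 29/31, 39/41, 89/91), placed distance minus true distance.
  Positive means boundary exaggeration, i.e. a left-digit effect.

## The cyclical power model

The model predicts the placing of target $x = x_d + x_u$ (decade part
plus unit digit) from the transformed magnitude
$s = x_d + x_u^{\delta}$:

$$y = \frac{(s - LB)^{\beta}}
  {(s - LB)^{\beta} + (UB - s)^{\beta}}\,(UB - LB) + LB$$

with curvature $\beta > 0$ and unit-digit weight $\delta$. In the
two-cycle structure the segment is chosen by the raw target value
($LB = 0, UB = 50$ for $x \le 50$, else $LB = 50, UB = 100$), so 0, 50
and 100 all act as anchors; the one-cycle structure uses the single
segment $[0, 100]$. The model is sometimes typeset with the
denominator factor written as "$\cdot\,0.5$" next to a trailing
"$\cdot\,100$"; the only reading consistent with $y = x$ at
$\beta = \delta = 1$, with $y(25) = 25$ and with the 0--100 range is
multiplication of the cyclical ratio by $0.5 \cdot 100 = UB - LB$,
which is what is implemented (the identity is pinned by tests to
$10^{-12}$).

The language modifier $\lambda$ gives each non-reference language its
own effective unit weight $\delta + \lambda_g L_g$ (indicator
$L_g \in \{0,1\}$). A $\lambda$ significantly different from zero is
the language-specificity result. `fit_power_model()` covers both the
two-language and the all-language variants; the latter carries one
$\lambda$ per comparison group and reduces exactly to the pair fit
when a language is dropped.

**Data preparation.** The model is fitted to median placing positions
per language and target over all retained responses (both
orientations, all participants pooled), targets above 20 only. With
eight responses per participant and target, the median is robust to
stray touches, so no response-level outlier trimming is applied. The
alternative pooling (per-participant medians first, then the median
across participants) is available via `pooling = "by_participant"`;
pooled is the default.

**Fitting.** Nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`), starting values $\beta = 1$, $\delta = 1$,
$\lambda = 0$; convergence tolerances `ftol = ptol = 1e-10`, at most
500 iterations; deterministic given the data. $\beta > 0$ is enforced
by optimizing $\log\beta$, with natural-scale standard errors by the
delta method from a central finite-difference Jacobian at the optimum.
Wald $t = \hat\theta / SE$ with $n - k$ residual df. If an optimizer
excursion pushes $s$ past a segment boundary (possible only for
effective $\delta \gtrsim 1.09$), $s$ is clamped just inside the
boundary. Cycle structures are compared by the Gaussian profile BIC
$n\ln(RSS/n) + k\ln n$.

```{r model-example, eval = FALSE}
cpm_predict(29, beta = 0.9, delta = 0.83)  # 26.075: 29 dragged below 26
med <- prepare_medians(preprocess_trials(trials))
fit <- fit_power_model(med, reference = "English")
summary(fit)   # Estimate / Std. Error / t value / Pr(>|t|) per parameter
```

## The synthetic cohort generator

`make_cohort()` emulates the study conditions end to end so the whole
pipeline, including preprocessing, is exercised on raw pixels:

* 50 printed targets $\times$ 4 repetitions $\times$ 2 orientation
  blocks (400 experimental trials plus 3 training trials per block);
  quasi-randomized order in which consecutive targets never share a
  unit digit and differ by at least 10, built by randomized sequential
  construction with restarts, deterministic per seed;
* timeouts at a configurable rate; a timed-out presentation carries no
  coordinates and is re-queued at the end of its block, where the
  adjacency constraints may be violated — exactly the one loophole the
  design itself has;
* responses: latent position = two-cycle prediction under the group's
  $(\beta, \delta)$ + `bias_offset` + $N(0, \sigma)$ trial noise,
  clipped to the physical line, converted to integer pixels under the
  participant's direction (sampled per orientation; roughly 0.98
  ascending horizontally and 0.8 vertically, following the observed
  choice frequencies), with Gaussian perpendicular scatter (SD 30 px,
  which makes perpendicular exclusions rare, of the order observed);
* response times: base + slope times the distance to the nearest
  anchor (50 or 100), purely so RT summaries have realistic structure;
  no claims attach to them.

Defaults are representative adult conditions for this design: 80/78/76
participants and per-language $(\beta, \delta)$ of $(0.89, 0.83)$,
$(0.91, 0.87)$ and $(0.89, 0.59)$ — mild curvature everywhere,
left-digit compression in all groups, the German unit weight slightly
above the English one and the Mandarin weight far below both; trial
noise SD 3 number-line units. `bias_offset` defaults to
0: the model at these parameters already implies a net underestimation
(closed form, e.g. `mean(cpm_predict(nle_targets, 0.89, 0.59) -
nle_targets)` $\approx -2.5$ units for the Mandarin parameters versus
$\approx -1.3$ for the English ones), reproducing the stronger Mandarin
underestimation and the teen/twenty asymmetry without a separate shift;
an additive offset on top would count the phenomenon twice, and —
because the fitted model has no intercept — push the offset-free NLS
fit towards degenerate unit weights. The offset remains available as an
explicit experimental dial.

Gaussian additive noise (rather than any particular empirical error
law) is chosen for parameter-recovery transparency; clipping mirrors
the physical line bounds and leaves medians unaffected at these noise
levels.

**What the generator does not emulate.** All participants of a group
share one $(\beta, \delta)$; there is no between-participant
heterogeneity in curvature, unit weight or overall shift. Group-level
*means* are therefore realistic, but participant-level SDs are
understated and group test statistics ($t$, $F$) come out far larger
than in behavioural data. Likewise, real responders are more veridical
within decades than the globally fitted model implies, so intra-decade
slopes measured on purely model-generated data sit below those of real
data even at matched $\delta$. Passing tests therefore validate the
estimators and their contracts, not the effect sizes one should expect
from human samples.

## Validation strategy and problem sizes

The suite validates each stage against independent oracles: closed-form
identities (model identity at $\beta = \delta = 1$; the $477/17$
inverted-pair constant; zero decade scores for affine responders),
hand-evaluated textbook formulas for the t statistics, exact
permutation/sign-flip oracles for the p-values, per-decade `lm()` fits
against the analytic model curve, and noise-free self-consistency plus
noisy parameter recovery for the NLS fit. Parameter recovery is run at
the study scale — 20 replicate cohorts of 80 participants per language
at noise SD 3, requiring all of $(\beta, \delta, \lambda)$ within
$\pm 0.05$ of truth in at least 90% of replicates — and design validity
over 100 seeds. These sizes keep the full suite around a minute on a
single core while testing the conditions the analyses are meant for.

## Known limitations

* The generalized-eta-squared CI construction is an assumption (see
  above); alternative constructions shift the bounds, not the point
  estimates.
* The decade-difference pair list is restricted to within-set pairs of
  true distance 2; other published variants (e.g. including pairs with
  one-digit members) need a custom `pairs` argument.
* `fit_power_model()` treats medians as homoscedastic observations;
  response counts per target are nearly balanced by design, so no
  weighting is applied.
* Per-participant cycle-structure assignment is out of scope by
  design: one configurable cycle structure is fitted for everyone,
  with the BIC comparison provided by `compare_cycles()`.
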