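---
title: "Risk-model-based heterogeneity-of-treatment-effect analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-model-based HTE analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The average treatment effect of a randomized trial can hide clinically
important variation: some participants may benefit substantially while
others gain nothing. One principled alternative to one-variable-at-a-time
subgroup analyses is *risk-based* subgrouping: predict each participant's
baseline risk of the outcome, partition the cohort into ordered risk
groups, and contrast the treatment effect across those groups. Because the
absolute benefit of a therapy with a constant relative effect grows
mechanically with baseline risk, heterogeneity must be examined on two
scales at once:

* **absolute scale** — the 5-year absolute risk reduction (ARR) per
  subgroup, from Kaplan–Meier event rates, with Cochran's Q testing whether
  the subgroup ARRs share a common value;
* **relative scale** — the hazard ratio per subgroup, with a joint Wald
  test on the treatment × subgroup interaction in a Cox model.

`riskhte` implements this workflow for three interchangeable
subgroup-generating strategies: an externally published stratified
proportional-hazards risk score, a bootstrap committee of classification
trees, and a probability-weighted random forest. A synthetic trial
generator with known, controllable heterogeneity provides the ground truth
that validates the whole machinery.

## The statistical core

### Kaplan–Meier ARR with Greenwood variance

Within each subgroup × arm cell the survival function is estimated by the
product-limit formula \(\hat S(t) = \prod_{t_i \le t}(1 - d_i/n_i)\) with
Greenwood variance \(\hat S(t)^2 \sum d_i / (n_i(n_i - d_i))\). The
subgroup ARR at horizon \(t\) (default 5 years) is

\[ \widehat{\mathrm{ARR}}_g = \hat F_{g,\mathrm{control}}(t) -
   \hat F_{g,\mathrm{treated}}(t), \qquad \hat F = 1 - \hat S, \]

with standard error \(\sqrt{v_{g,\mathrm{control}} + v_{g,\mathrm{treated}}}\)
and a symmetric normal-approximation confidence interval. This is the
standard construction consistent with symmetric ARR intervals; a
complementary log-log transform would be an alternative, and exact
agreement with any specific published interval width should not be assumed.
Without censoring the construction collapses to a difference of binomial
proportions with summed binomial variances, which the test suite verifies
against that oracle. The number needed to treat is `1/ARR`, with bounds
equal to the order-swapped reciprocals of the ARR bounds, reported only
when the ARR interval excludes zero.

### Cochran's Q across subgroups

The subgroup ARRs enter a fixed-effect inverse-variance meta-analysis:
weights \(w_g = 1/\mathrm{SE}_g^2\), pooled effect
\(\bar\theta = \sum w_g\theta_g / \sum w_g\), and
\(Q = \sum w_g(\theta_g - \bar\theta)^2 \sim \chi^2_{G-1}\) under
homogeneity. Fixed-effect weighting is the conventional definition of Q; a
random-effects formulation is out of scope.

### Cox interaction test

The relative-scale test fits
`Surv(time, event) ~ arm * factor(group)` by partial likelihood with
**Efron tie handling** (ties are likely when times are recorded coarsely)
and evaluates the joint Wald chi-squared on the \(G-1\) interaction
coefficients. Per-subgroup hazard ratios are re-estimated by separate
within-subgroup Cox fits, which is how per-group effects are usually
reported alongside the interaction test.

## The three subgroupers

**Extant PH score.** A published stratified linear proportional-hazards
score is consumed as a coefficient table (per-stratum coefficients,
centering values, and 5-year baseline survival); predicted risk is
\(1 - S_0(5)^{\exp(lp)}\). The score is *applied*, never re-fitted — the
package deliberately has no code to estimate it.

**Quintile partition.** Risk scores are cut into ordered groups by *rank*,
not by value thresholds: sorted by `(score, id)` and sliced into contiguous
blocks whose sizes differ by at most one (larger blocks at the high-risk
end). Rank-cutting is forced by the bookkeeping requirement that a test
set of 1,150 yield five groups of exactly 230; the `(score, id)` sort makes
tie-breaking deterministic. Any strictly monotone transform of the scores
yields the identical partition.

**Tree committee.** Thirty bootstrap resamples of the oversampled training
half each grow an `rpart` classification tree (binary Gini splits), tuned
over minimum leaf size with rpart's internal cross-validation and pruned by
cost-complexity to at most 6 terminal nodes. Each tree is scored on the
untouched test half and the tree with *median* test accuracy represents
the committee; for an even committee size the lower median (the
\(\lceil B/2\rceil\)-th order statistic) is used, so selection is
deterministic. Subgroups are the selected tree's leaves, renumbered by
ascending training event probability so the highest group index is always
the highest-risk leaf. Leaf assignment for new data uses an explicit
descent over the fitted tree's split structure (complete cases only, so
surrogate splits are never needed).

**Probability-weighted forest.** One hundred bagged trees with per-split
random feature subsetting, each limited to 10 terminal nodes. The trees
are grown in *regression* mode on the 0/1 label: a regression tree's leaf
value is exactly the leaf's positive-class frequency, so the ensemble mean
implements a probability-weighted vote — each tree contributes its
predicted probability rather than a hard class vote. The feature-subset
size and minimum leaf size are tuned by 10-fold cross-validation
maximizing classification accuracy at the 0.5 threshold. Forest scores
then feed the same quintile partition.

Both machine-learning models ignore time-to-event and censoring by design:
they classify "experienced the outcome during follow-up" (censored-early
participants count as non-events). This is a deliberate simplification of
the modelled quantity, not an oversight, and it is one reason their
discrimination can trail the PH score's.

## Cohort preparation

Complete-case filtering (no imputation), then an outcome-stratified 50/50
split: test counts are `round(stratum size × fraction)` per event stratum
(R's round-half-to-even), so both halves retain the cohort's event
proportion up to rounding. The training half — never the test half — is
balanced by oversampling event rows with replacement until the classes
match; duplicates keep their original id plus a `replicate` counter so
resampling bookkeeping stays auditable. The pipeline asserts that no test
id ever reaches oversampling, bootstrapping, or tuning.

The extant-score arm of the pipeline scores the **full** filtered cohort
(the published model needs no training data), while the machine-learning
arms are assessed and subgrouped on the test half only. This asymmetry is
intentional and logged; `linear_ph_cohort = "test"` restricts all models
to the test half for an apples-to-apples comparison.

## Model assessment

Threshold metrics (accuracy, sensitivity, specificity, PPV) are computed
at a 50% predicted-risk threshold with a normal-approximation interval on
each metric's own denominator (a Wilson option is provided; bootstrap
intervals over the committee replicates are a natural alternative but the
analytic form is the default). PPV is reported as undefined — not zero —
when nothing is predicted positive.

Discrimination under censoring uses the time-dependent cumulative/dynamic
AUC at the horizon with the nearest-neighbour bivariate-survival
estimator: conditional survival given the score is a Kaplan–Meier estimate
over a symmetric score-percentile window of half-width
`span = 0.25 · n^(-1/5)` (a common smoothing-rate convention; results
should be checked for sensitivity to it). Only score ranks enter, so the
estimate is invariant under monotone transforms, and without censoring
before the horizon it converges on the Mann–Whitney concordance — both
properties are tested.

Calibration compares, per subgroup, mean predicted risk against the
Kaplan–Meier observed event rate at the horizon.

## The synthetic trial generator

The generator emulates a mid-size primary-prevention trial: ~2,300
participants after exclusions, 1:1 allocation, about 10.5% cumulative
incidence of a composite time-to-event outcome over ~7 years of follow-up,
and a graded baseline-risk structure driven by a mix of continuous and
binary covariates.

* **Event model.** Weibull proportional hazards,
  \(h(t) = h_0(t)\exp(lp + \mathrm{arm}\cdot\log\mathrm{HR}(p))\), with
  shape 1 (exponential) by default — the simplest model consistent with a
  semi-parametric analysis; nothing in the package assumes the shape.
* **Covariates.** Six standard-normal and four binary covariates
  (prevalences 0.50/0.35/0.20/0.15) with log hazard ratios spanning 0–0.5.
  These are invented defaults chosen to give a clearly graded risk
  distribution; they do not reproduce any real cohort's covariate table.
* **Censoring.** Administrative at a 7-year horizon, plus optional
  independent exponential dropout (off by default, since the emulated
  design's censoring pattern is not public knowledge). The horizon is an
  assumption and is flagged in the scenario config.
* **Calibration.** The Weibull scale is not a free parameter: it is found
  by monotone root search so that the *expected* observed-event fraction
  (closed form without dropout; an integration-by-parts quadrature with
  it) hits the target within 0.005.
* **Treatment effect.** Three modes: none; a constant log hazard ratio
  (no relative-scale heterogeneity, yet ARR still rises with baseline
  risk — the dissociation the two test scales are meant to expose); and a
  risk-graded effect, log HR \(= \theta_0 + \theta_1 p\) with \(p\) the
  latent risk percentile, default \((0.2, -1.0)\) so benefit concentrates
  in the highest-risk fifth while the lowest-risk participants receive
  none or slight harm. Any monotone map would do; the linear one is
  recorded in the config and keeps true subgroup ARRs strictly increasing.
* **Truth tables.** Each simulated trial carries per-participant true
  5-year risks under both arms, so recovery experiments compare estimates
  against exact subgroup-level true ARRs.

What the generator does **not** emulate: real covariate distributions and
their correlations, competing risks, non-proportional hazards, informative
censoring, or measurement error. Passing recovery tests therefore shows
the machinery is correct under its stated model, not that any particular
real-data conclusion is reproduced.

## Numerical and design choices

* **Null for the Q-size experiment.** The type-I-error simulation runs at
  hazard ratio 1. A constant HR ≠ 1 is *not* a null for the absolute
  scale — with graded baseline risk it induces genuine ARR heterogeneity —
  so it is used where it belongs: showing the relative-scale test stays
  near nominal while the absolute gradient is real.
* **Small subgroups.** Kaplan–Meier contrasts need participants in both
  arms; subgroups with fewer than 10 per arm (configurable) either raise
  an error or are merged into their lower-risk neighbour, and the same
  merged grouping is used consistently for ARR, calibration, and the
  interaction test.
* **Degenerate inputs.** All-censored samples keep \(\hat S \equiv 1\)
  with zero variance; the Greenwood variance is reported as 0 where
  \(\hat S\) reaches 0; horizons beyond the last observed time return the
  last estimate with an explicit extrapolation flag; a bootstrap resample
  with one outcome class is redrawn and the retry logged.
* **Determinism.** Every stochastic step (generation, splitting,
  oversampling, bootstraps, forests) takes a seed and is byte-reproducible
  given it; fitted-model reproducibility is carried by seeds plus recorded
  tuning tables rather than binary model dumps.
* **Multiplicity.** No correction is applied across the three models'
  tests, matching common practice for method-comparison analyses; treat
  the per-model p-values accordingly.

## Problem sizes in the test suite

The bundled tests exercise the operating characteristics at the scale the
package targets: Q-test size and power use 2,300-participant trials with
500 replicates (the dissociation experiment also runs 500 replicates per
arm of the comparison); Cox interaction size uses 100 trials of 4,000; the
exhaustive Kaplan–Meier oracle covers every censoring pattern on up to six
subjects plus tied-time patterns. The acceptance script repeats the
cohort-scale analysis on a simulated 2,411-row cohort (120 rows planted
missing) and summarizes the replicate experiments at 150–200 replicates.

## Known limitations

* The ARR interval is the plain normal approximation; near 0 or 1 event
  rates its coverage degrades (no log-log or arcsine option yet).
* The interaction test and Q test treat the subgroup assignment as fixed;
  uncertainty from estimating the risk model itself is not propagated.
* Classification-based subgroupers discard censoring information; survival
  trees and random survival forests would use it but are out of scope.
* The nearest-neighbour AUC uses a single global span; no local bandwidth
  adaptation.
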