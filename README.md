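# riskhte

Risk-model-based subgroup analysis of treatment-effect heterogeneity (HTE)
in randomized trials with a time-to-event outcome.

Average treatment effects can hide clinically important variation. A
principled way to look for it is to predict each participant's baseline
risk of the outcome, partition the cohort into ordered risk groups, and
contrast the treatment effect across the groups on two scales:

* **absolute scale** — the 5-year absolute risk reduction (ARR) per
  subgroup from Kaplan–Meier event rates,
  `ARR_g = F̂_g,control(5) − F̂_g,treated(5)`, with Greenwood standard
  errors and a fixed-effect Cochran's Q test
  (`Q = Σ w_g (ARR_g − ARR̄)², w_g = 1/SE_g²`, `df = G − 1`) for whether
  the absolute benefit varies by subgroup;
* **relative scale** — per-subgroup hazard ratios and the joint Wald
  chi-squared on the treatment × subgroup interaction in a Cox
  proportional-hazards model (Efron ties).

Because absolute benefit grows mechanically with baseline risk even when
the hazard ratio is constant, the two scales can disagree — and that
dissociation is exactly what this package is built to expose.

Three interchangeable subgroup-generating strategies are provided:

1. **Extant PH score** — an externally published, stratified linear
   proportional-hazards risk score read from a coefficient table and
   applied (never re-fitted): `risk = 1 − S₀(5)^exp(lp)`;
2. **Decision-tree committee** — classification trees on 30 bootstraps of
   the oversampled training half, pruned to ≤ 6 leaves, represented by the
   tree with median test accuracy; subgroups are its leaves;
3. **Probability-weighted random forest** — 100 bagged trees capped at 10
   leaves whose votes are weighted by predicted positive-class
   probability; forest scores feed the same rank-quintile partition.

Model quality is assessed with threshold classification metrics,
nearest-neighbour time-dependent AUC at the horizon, and per-subgroup
calibration. A synthetic randomized-trial generator (Weibull proportional
hazards, calibrated event fraction, controllable risk-graded treatment
effects with exact per-participant truth) backs parameter-recovery and
operating-characteristic experiments.

## Worked example

Simulate a 2,291-participant trial whose treatment benefit is concentrated
in the highest-risk fifth, then run the full pipeline with all three
subgroupers (the simulator's own risk model plays the role of the
published score):

```r
library(riskhte)

scenario <- trial_scenario(n_participants = 2291, effect = "risk_graded",
                           seed = 11)
trial <- generate_trial(scenario)
trial
#> <simulated_trial>
#>   2291 participants (1146 treated), 230 events (10.0%), scale = 99.09 y

report <- run_hte_analysis(
  trial$participants,
  ph_model = true_ph_model(trial),
  seed = 5, small_groups = "merge"
)
report
#> <hte_report>
#>   input 2291, excluded 0, analyzed 2291 (train 1146 / test 1145)
#> # A tibble: 3 x 9
#>   model     n_subgroups accuracy   auc top_arr top_nnt q_statistic      q_p
#>   <chr>           <int>    <dbl> <dbl>   <dbl>   <dbl>       <dbl>    <dbl>
#> 1 linear_ph           5    0.900 0.722   0.162    6.17        22.0 0.000203
#> 2 tree                5    0.668 0.591   0.126    7.91        13.2 0.0105
#> 3 forest              5    0.734 0.691   0.191    5.24        17.3 0.00171
```

Each row is one subgrouping strategy: `accuracy` and `auc` are test-half
discrimination, `top_arr` is the estimated ARR in the highest-risk
subgroup (16.2 percentage points for the PH score here), `top_nnt` its
number needed to treat (6.2), and `q_p` the Cochran's Q p-value — all
three models detect the absolute-scale heterogeneity this scenario truly
contains. The per-subgroup table shows the gradient directly:

```r
report$models$linear_ph$arr
#>   risk_group n_control n_treated rate_control rate_treated       arr  arr_lo arr_hi
#> 1          1       234       224       0.0171      0.00893  0.008165 -0.0125 0.0288
#> 2          2       217       241       0.0323      0.03320 -0.000937 -0.0336 0.0317
#> 3          3       232       226       0.0776      0.04425  0.033338 -0.0103 0.0770
#> 4          4       218       240       0.0826      0.08750 -0.004931 -0.0560 0.0462
#> 5          5       244       215       0.2459      0.08372  0.162181  0.0967 0.2277
```

Only the top quintile's interval excludes zero — the benefit sits where
the simulated truth put it, as the oracle confirms:

```r
true_arr_by_risk_group(trial)
#>   risk_group   n true_risk_control true_risk_treated true_arr
#> 1          1 458            0.0257            0.0279 -0.00225
#> ...
#> 5          5 459            0.2106            0.1103  0.10035
```

`tidy(report)` returns the combined ARR table, `glance(report)` the
one-row-per-model summary above, `autoplot(report)` a forest plot of
subgroup ARRs, and `flow_accounting(report)` the participant-flow counts.
`write_hte_report()` serializes everything to JSON. A thin command-line
wrapper lives at `inst/cli/hte.R` (`run`, `simulate`, `replicate`
subcommands).

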