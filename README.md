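# ncctrial

Operating characteristics of two-stage platform trials that add an
experimental arm mid-trial, with or without **non-concurrent control
data** in the added arm's analysis.

## The scientific problem

A platform trial compares several experimental treatments against one
shared control arm and may open a new arm while recruitment is ongoing.
Control patients enrolled before the new arm opened are *non-concurrent*
with it. Including them when estimating the new arm's effect
δ<sub>K+1</sub> = μ<sub>K+1</sub> − μ<sub>0</sub> increases precision —
but if the outcome drifts over calendar time, those early controls are
systematically different, and the estimate inherits the drift as bias.
`ncctrial` is for trial statisticians who need to quantify that
trade-off before writing an analysis plan.

The package implements, for the response model
X<sub>j</sub> = μ<sub>T_j</sub> + τ(j) + ε<sub>j</sub>,
ε<sub>j</sub> ~ N(0, σ²) with σ² known and τ a linear
(λ(j−1)/(n<sub>tot</sub>−1)) or step (λ·I(stage 2)) calendar-time trend:

* **Design model** — stage-wise sample sizes derived from the *timing of
  addition* n₀₁/n₀ (`trial_design`, `derive_stage_sizes`);
* **Simulator** — patient-level trials under restricted within-stage
  randomization (`simulate_trial`);
* **Six analyses** — independent z-tests with all or concurrent-only
  controls; generalized least squares on the stage-wise mean differences
  with its exact shared-control covariance, in the all-control
  (`WLS_all`) and concurrent-only (`WLS_s2`) variants; and patient-level
  regressions adjusting for enrolment order (`Ma1`, `Mb1`) or a stage
  effect (`Ma2`, `Mb2`);
* **Closed-form operating characteristics** — z-test power, GLS
  variances and marginal power, and the *borrowing of strength*
  BoS = (V₀ − V<sub>a</sub>)/V₀, the proportional variance reduction
  bought by the non-concurrent controls;
* **Monte-Carlo engine** — bias, type-I error, marginal power and rMSE
  per method over the (timing × added-arm size × trend) scenario grid.

## Worked example

A trial with n₀ = n₁ = 550 adds a 550-patient arm late (timing 0.75),
and the outcome carries a step trend of 8% of a standard deviation:

```r
library(ncctrial)
design <- trial_design(n_arm = c(550, 550), timing = 0.75, n_new = 550)
design
#> Two-stage platform trial: K = 1 initial arm(s) + control, arm 2 added at timing 0.75
#> sigma^2 = 1, one-sided alpha = 0.05
#> Stage-wise sample sizes:
#>       s1  s2
#> arm0 413 137
#> arm1 413 137
#> arm2   0 550

borrowing_of_strength(design)
#> [1] 0.4297607
round(wls_marginal_power(design, c(0.15, 0.15), "s2"), 3)
#> delta_1 delta_2
#>   0.800   0.592
```

Including the 413 non-concurrent controls would cut the added-arm
contrast variance by 43% (BoS), lifting its marginal power from 0.592 to
0.800 — *if* no trend is present. With the trend, that gain costs bias:

```r
summ <- run_scenario(design, effect_spec(0, c(0.15, 0.15)),
                     trend_spec("step", 0.08),
                     n_reps = 2000, seed = 1,
                     methods = c("WLS_all", "WLS_s2", "Ma1"))
summ[summ$arm == 2, c("method", "bias", "reject_rate", "rmse")]
#>    method    bias reject_rate  rmse
#> 2 WLS_all 6.0e-02        0.96 0.086
#> 4  WLS_s2 2.5e-06        0.59 0.080
#> 6     Ma1 2.4e-02        0.77 0.078
```

The all-control GLS is biased by ≈ λ × timing = 0.06 and its rejection
rate (nominally 0.80 at δ = 0.15) is inflated to 0.96; the
concurrent-only analysis stays unbiased at its honest 0.59 power; the
enrolment-order adjustment lands in between, because a linear term
cannot fully absorb a step.

Analytic curve tables for power/BoS against the timing of addition come
from `oc_curves()`; `reproduce_table1()`,
`reproduce_power_and_error_surfaces()` and `reproduce_rmse_tables()` run
the full Monte-Carlo study. A command-line front end with verbs
`simulate`, `oc`, `grid` and `table1` is installed at
`inst/cli/ncctrial.R`.

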