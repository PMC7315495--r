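---
title: "Models and methods: non-concurrent controls in a trial that adds an arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: non-concurrent controls in a trial that adds an arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncctrial)
```

## The problem

A platform trial evaluates several experimental treatments against one
shared control under a master protocol, and may open a new experimental
arm while recruitment is ongoing.  Control patients enrolled *before* the
new arm opened are **non-concurrent** with it; those enrolled after are
**concurrent**.  Using the non-concurrent control data when analysing the
added arm buys precision — the control sample backing the comparison grows
— but risks bias whenever the outcome drifts over calendar time, because
the early control patients were treated under different conditions than
any patient on the new arm.

`ncctrial` studies this trade-off in the simplest setting that exhibits
it: a two-stage trial with `K` initial experimental arms plus control, and
one arm added at the end of stage one.

## Response model

Patient `j` (global enrolment order, stage two continuing the count)
receives arm `T_j` and responds

$$X_j = \mu_{T_j} + \tau(j) + \epsilon_j, \qquad
  \epsilon_j \overset{iid}{\sim} N(0, \sigma^2),$$

with $\sigma^2$ treated as **known** throughout.  Two fixed trend shapes
$\tau(\cdot)$ are implemented:

* **linear**: $\tau(j) = \lambda\,(j-1)/(n_{tot}-1)$, a drift from 0 to
  $\lambda$ over the whole trial ($n_{tot}$ counts every patient,
  including the added arm);
* **step**: $\tau(j) = \lambda\, I(\text{stage}(j) = 2)$, a level shift
  affecting every stage-two patient.

With $\sigma^2 = 1$, $\lambda$ is the trend magnitude as a fraction of a
standard deviation.  Negative $\lambda$ is allowed and mirrors the
positive case (deflation instead of inflation of rejection rates).

Allocation uses **restricted randomization within each stage**: each
stage's allocation sequence is one uniformly random permutation of a
multiset holding exactly the planned number of patients per open arm, so
per-cell counts are exact in every realisation.  The procedure name fixes
the counts, not the block structure; we use one maximal permuted block per
stage, the weakest scheme that guarantees exact counts.  This matters
scientifically: exact within-stage balance is what makes the *initial*
arms' contrasts trend-robust, since both arms of a stage-wise difference
absorb the same average trend.

## The six analysis approaches

Let $\bar X_{k.s}$ be the stage-$s$ mean of arm $k$ and
$\bar X_k = (n_{k1}\bar X_{k.1} + n_{k2}\bar X_{k.2})/n_k$.  All tests are
one-sided ($H_{0k}: \mu_k = \mu_0$ vs $\mu_k > \mu_0$) at level $\alpha$,
marginal (per hypothesis, no multiplicity adjustment), and use the known
$\sigma^2$ — z-statistics, never t.

1. **Independent z-test** (`z_test`): compares sample means, either
   against all control data or (for the added arm) only stage-two
   controls.
2. **GLS on stage-wise mean differences** (`wls_stagewise`): the
   contrasts $\bar X^{(k)}_s = \bar X_{k.s} - \bar X_{0.s}$ for the
   initial arms, plus for the added arm either
   $\bar X_{K+1,2} - \bar X_{0.2}$ (**WLS_s2**, concurrent only) or
   $\bar X_{K+1,2} - \bar X_0$ (**WLS_all**, all control data), are
   jointly modelled with their exact covariance: variances
   $\sigma^2/n_{ks} + \sigma^2/n_{0s}$, covariance $\sigma^2/n_{0s}$
   within a stage (shared control), zero across stages, and
   $\sigma^2/n_0$ between the all-control contrast and every other.
   $\hat\delta = (D'\Sigma^{-1}D)^{-1}D'\Sigma^{-1}y$ with covariance
   $(D'\Sigma^{-1}D)^{-1}$.  The joint model is more efficient than the
   independent z-test because it exploits the shared control.
3. **Patient-level regressions** (`regression_fit`): OLS with arm
   indicators and either a linear term in enrolment order (`Ma1`, on all
   arms; `Mb1`, on control + added arm only) or a stage indicator
   (`Ma2`, `Mb2`).  Control is the reference level absorbed by the
   intercept; the `Mb` fits use only the control and added-arm rows,
   which is how "control both stages + new arm" is operationalised.
   Coefficient covariance is $\sigma^2(X'X)^{-1}$.

Two structural identities the test suite asserts realisation-by-
realisation rather than statistically: `Ma2`'s arm coefficients equal the
`WLS_s2` GLS estimates to machine precision (the stage indicator soaks up
exactly the information the concurrent-only contrast discards), and `Mb2`
is the saturated three-cell model, so its added-arm coefficient is
literally $\bar X_{K+1,2} - \bar X_{0.2}$.  We verified the `Ma2`
equivalence numerically before freezing it as an equality test at
tolerance $10^{-10}$; the relationship is sometimes described merely as
"similar", but for these balanced two-stage designs it is exact.

## Metrics

For each method and hypothesis the Monte-Carlo engine reports **bias**,
**rejection rate** (type-I error under the null regime, marginal power
under the alternative), and
$\text{rMSE} = \sqrt{\text{bias}^2 + \text{variance}}$ using the
Monte-Carlo population variance, so the identity holds exactly in the
output.  The analytic module adds **borrowing of strength**,

$$BoS = (V_0 - V_a)/V_0,$$

the proportional reduction in $var(\hat\delta_{K+1})$ from including
non-concurrent controls ($V_0$: concurrent-only GLS; $V_a$: all-control
GLS).  BoS is defined only for the added arm — the concurrent/
non-concurrent split is relative to it — and requesting it for an initial
arm is an error.

## Study conditions and generator defaults

The simulator's defaults are the study conditions themselves, not tuning
knobs: $K = 1$, $n_0 = n_1 = 550$ (chosen so the z-test for the initial
arm has 80% power at one-sided 5% for $\delta = 0.15$), $\sigma^2 = 1$,
balanced stage-wise allocation $n_{11} = n_{01}$, timing of addition
$n_{01}/n_0 \in \{0.25, 0.5, 0.75\}$, added-arm size
$n_{22} \in \{n_{02}, n_0, 2n_0\}$, and trend magnitudes
$\lambda \in \{0.02, 0.04, 0.06, 0.08\}$ for both families.  Effects are
$\delta_1 = \delta_2 = 0.15$ under the alternative and 0 under the null.

Numerical conventions worth stating:

* **Fractional stage splits.** Timing 0.25 with $n_0 = 550$ gives
  $137.5$; we round half-up (never banker's rounding), so $n_{01} = 138$.
  A one-patient shift changes no reported quantity at its displayed
  precision.
* **Degenerate variance.** With $\sigma^2 = 0$ the z-statistic is defined
  as $\pm\infty$ by the sign of the estimate (0 when the estimate is 0),
  so noise-free fixtures exercise the full decision path instead of
  producing `NaN`.
* **Raw enrolment order.** `Ma1`/`Mb1` use `j` uncentred and unscaled;
  centring would change only the intercept.
* **Zero reporting.** In the absolute-bias table, values below $10^{-3}$
  are displayed as 0: at $10^4$ replicates that is the Monte-Carlo noise
  floor of an unbiased estimator, and reporting its digits would be
  noise.  The threshold is an argument (`zero_tol`), not a constant.
* **Seeds.** Every scenario's stream is derived from the master seed and
  the scenario's coordinates (timing, added-arm size, trend family,
  magnitude, regime) by a small deterministic hash, so any subset of the
  grid, run in any order, reproduces the full run's numbers bit-for-bit.
  All seeded entry points restore the caller's RNG state.
* **Edge design `K = 0`.** A design with only control plus the added arm
  is allowed; there the GLS model collapses to the corresponding z-test
  exactly, which the tests use as a closed-form limit check.
* **Timing grid.** Analytic curve generators default to a step of 0.05
  over (0.1, 0.9); the resolution is a parameter.
* **Trend application.** The trend enters at response-generation time
  inside the one-pass simulator; adding it to responses afterwards would
  be algebraically identical.

## What the Monte-Carlo study shows — and what it cannot

Problem sizes: the packaged study runs $10^4$ replicates per scenario
(bias Monte-Carlo standard error $\approx 6\times10^{-4}$ for the
all-control GLS, rejection-rate standard error $\approx 0.002$ at the 5%
level), which resolves every tabulated value at its displayed precision.
Larger replicate counts only shrink these errors at the usual
$\sqrt{n}$ rate, which `run_scenario(n_reps = ...)` exposes.

The generator emulates exactly the idealised trial the closed-form
results describe: normal responses with known common variance, fixed
deterministic trends, exact restricted randomization, all arms finishing
simultaneously, no dropout, no interim looks.  Passing tests therefore
validate the *estimators and their operating characteristics under the
stated model*; they say nothing about unequal variances, non-normal or
binary outcomes, staggered recruitment ends, stochastic or non-monotone
drifts, or estimated $\sigma^2$ — all outside scope.  In particular the
step/linear dichotomy brackets, but does not exhaust, real calendar-time
behaviour; the headline caveat (a linear adjustment does not protect
against a non-linear trend) is exactly why both families are built in.

## Known limitations

* Two stages and one added arm only; multiple additions or more than two
  stages would need a richer covariance structure.
* Marginal inference only: no Dunnett-style simultaneous critical values,
  although the GLS joint covariance needed to build them is returned.
* No closed-form power under a trend (the trend's effect on rejection
  rates is a simulation question here).
* The t-test for unknown $\sigma^2$ is deliberately not implemented;
  every reported variance assumes $\sigma^2$ known.
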