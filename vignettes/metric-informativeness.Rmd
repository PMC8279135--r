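---
title: "Comparing the informativeness of regression evaluation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the informativeness of regression evaluation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regeval)
```

## The question

Given a vector of actual target values $Y_1,\dots,Y_m$ and a vector of
predictions $X_1,\dots,X_m$, many rates summarize how good the
prediction is: the coefficient of determination

$$R^2 = 1 - \frac{\sum_i (X_i - Y_i)^2}{\sum_i (Y_i - \bar Y)^2},$$

the error means MSE, RMSE, MAE, the relative-error mean MAPE, and the
bounded symmetric relative error

$$\mathrm{SMAPE} = \frac{1}{m}\sum_i
  \frac{|X_i - Y_i|}{(|X_i| + |Y_i|)/2} \in [0, 2].$$

Because SMAPE's polarity is inverted relative to $R^2$, the package also
carries the complementary normalized SMAPE,
$\mathrm{cnSMAPE} = 1 - \mathrm{SMAPE}/2 \in [0,1]$, so both rates read
"1 = perfect". These rates do not merely rescale one another: on the
same predictions they can disagree about which of two models is better.
`regeval` implements the rates with pinned-down edge-case semantics,
the constructions that expose their disagreements, and a repeated-holdout
harness that measures ranking disagreement on synthetic clinical-style
data.

## Metric conventions and degenerate inputs

Numerical conventions, fixed once and used everywhere:

* **Normalization.** MST (the $R^2$ denominator) and MSE are both
  mean-normalized, i.e. carry a $1/m$ factor. The factors cancel in the
  ratio, so $R^2 = 1 - \mathrm{MSE}/\mathrm{MST}$ holds exactly; the
  test suite asserts this identity to 12 significant digits on random
  series.
* **SMAPE scale.** Stored as a fraction in $[0,2]$; percentage displays
  multiply by 100. The two conventions are computationally equivalent.
* **SMAPE at $X_i = Y_i = 0$.** The term is defined as 0. The ratio is
  formally $0/0$, but an exact match carries no error, and this choice
  is what preserves "SMAPE $= 0$ iff the prediction is exact". Any
  other zero-denominator case cannot arise: if exactly one of the pair
  is 0 the term is $2$, the maximum.
* **MAPE with zero actuals.** A hard undefined-metric error from
  `mape()`: silently dropping offending points would change $m$ and
  quietly redefine the metric. In the batch report (`evaluate_all()`)
  MAPE is instead flagged `NA` with a reason string, so the other six
  rates survive serialization.
* **$R^2$ with a constant actual vector.** Undefined-metric error; the
  denominator is zero and no value is defensible.
* **Errors carry classes.** Degenerate inputs raise conditions of class
  `regeval_undefined_metric` or `regeval_domain_error`, so callers can
  distinguish mathematical undefinedness from misuse.

Two printed-digit worked examples ship as fixtures
(`worked_example_r2_zero()`, `worked_example_smape_max()`): a 10-point
series with MSE = MST = 1051.511 and hence $R^2 \approx 10^{-7}$ —
numerically zero without the prediction tracking anything — and a
sign-alternating series whose all-opposite-sign prediction drives every
SMAPE term to its maximum, SMAPE = 2, regardless of magnitudes.

## The use cases

Each construction isolates one way the rates diverge; all are exactly
reproducible, and the published reference values are pinned in the test
suite at their printed precision.

* **UC1** (`build_uc1(j)`): truth $1,\dots,100$; the first $j \le 20$
  entries at indices $\equiv 1 \pmod 5$ (1-based) are predicted as 0.
  Each zeroed point contributes the maximal SMAPE term, so
  cnSMAPE $= 1 - j/100$ falls linearly, while
  $R^2 = 1 - \sum_{k<j}(5k+1)^2 / 83325$ collapses much faster — at
  $j = 20$, cnSMAPE still reads 0.80 while $R^2$ is 0.236.
* **UC2** (`build_uc2(variant)`): ten zeroed points at the start
  (indices 1–10), middle (51–60) or end (91–100) of the same line.
  cnSMAPE is 0.9 in all three cases — SMAPE counts mismatches but not
  their magnitude — while $R^2$ reads 0.995, 0.6293 and −0.0955. The
  start variant zeroes indices 1..10: with only nine zeroed points
  neither printed value (0.995, 0.9) is reproducible, so the ten-point
  reading is the consistent one.
* **UC3** (`build_uc3()`): twenty noisy points on $y = x$, scored
  against the clean line (correct model) and against the minimal-degree
  polynomial through the first ten noisy points (wrong, overfit model).
  Through ten points the interpolant has degree at most 9 and is
  evaluated with the barycentric Lagrange scheme, which is stable on
  the nodes and valid beyond them, where this construction needs it.
  The wrong model is perfect on its own prefix ($N \le 10$: both rates
  1) and then explodes; for $N > 10$ its cnSMAPE is bounded below by
  $10/N$ (first ten terms ≈ 0, later terms ≤ 2) and so never falls
  under 0.5, while its $R^2$ plunges through $-10^2 \dots -10^{10}$.
  The noise is i.i.d. Gaussian with mean 0 and sd 0.5 under a fixed
  default seed (42) — a "small amount" relative to unit grid spacing.
  The exact noisy values are therefore a modelling choice, and only the
  prefix-perfection, the $10/N$ bound and the monotone collapse are
  asserted, not specific wrong-model magnitudes.
* **UC4** (`build_uc4()`): truth $(1,1,1,1,1,2,3)$ predicted as all 1.
  $R^2 = -0.346$ (worse than the mean predictor) while cnSMAPE reads
  0.881 — a "good" score for a regression that predicts a constant.
* **UC5** (`enumerate_uc5()`): all $5^5 = 3125$ integer predictions of
  $(1,2,3,4,5)$, in lexicographic order, each scored with both rates;
  `filter_uc5_nonnegative()` keeps the non-negative-$R^2$ subset used
  for scatter plots. The identity is the unique entry with $R^2 = 1$,
  and entries such as $(1,2,3,5,2)$ — $R^2 = 0$, cnSMAPE $= 0.89$ —
  exhibit maximal discordance.

## The synthetic clinical scenarios

The repeated-holdout study runs on generated datasets that mirror the
*structure* of two public EHR cohorts without requiring any download:

* `scenario_preset("hepatitis-like")`: 615 samples, ordinal target
  coded 0–3 with counts 540/24/21/30 (87.8% healthy controls), 12
  numeric features, 1% missing cells;
* `scenario_preset("obesity-like")`: 2111 samples, target coded 1–7
  with counts 272/287/351/297/324/290/290, 16 features, complete.

Per-level counts are fixed by largest-remainder apportionment, so the
class balance is exact, not sampled. Features are class-conditional
Gaussians: a sample at (0-based) level index $k$ has features
$\mathcal N(k \cdot s, 1)$, where the separation $s$ (default 1) tunes
how learnable the target is; $s = 0$ gives pure noise, on which a
constant predictor's held-out $R^2$ is ≈ 0, and held-out fit increases
monotonically in $s$ (both properties are tested). This feature model
is deliberately generic — it does not emulate real covariate
distributions (lab values, BMI, ...), their correlations, or informative
missingness. Passing tests therefore demonstrate the metric and ranking
machinery, not clinical realism: on real data the three regressors'
absolute scores and orderings may differ.

Missing cells (the hepatitis-like preset masks 1% of feature cells
completely at random; the real cohort's rate and mechanism are not on
record) are filled by **column-mean imputation** — a deliberately
simple, deterministic stand-in, not predictive mean matching or any
multiple-imputation scheme; the pipeline's subject is the metrics, and
a fancier imputer would only blur attribution.

## The repeated-holdout pipeline

One run (`run_single()`): shuffle, split 80/20 (train size
$\lfloor 0.8 n \rfloor$; all models share the identical split), fit
each model on the training fold, score its test-fold predictions with
every rate. `run_repeated()` executes $n$ runs (default 100) with
per-run seeds drawn once from the master seed, averages each rate per
model, and derives each metric's model ordering from the means — higher
is better for $R^2$/cnSMAPE, lower for the rest, ties broken by method
name so orderings are deterministic.

The default model set is the classic tabular trio — `stats::lm`,
`rpart` regression tree (cp = 0.01), `randomForest` (ntree
configurable, default 100) — consumed through the `model_spec()`
contract: `fit(features, target, seed)` returning a prediction
function, so any learner can be bound without touching the pipeline.

Two design points worth noting:

* **Zero-coded targets.** The hepatitis-like preset codes its target
  0–3, on which MAPE is undefined. The pipeline shifts such targets up
  by a constant (0–3 → 1–4) before training and evaluation and reports
  the shift with a message. The shift leaves every within-run ordering
  by squared-error rates intact.
* **Averaged-then-ranked vs per-run.** Rankings in the result table
  come from per-metric means over runs (the per-run values are kept in
  `$per_run`). Within any single run the orderings induced by $R^2$,
  MSE and RMSE coincide exactly — RMSE is a monotone transform of MSE,
  and $R^2$ a decreasing affine transform of it for a fixed test fold —
  and the suite asserts this across 100 scenario runs. Averaging over
  different splits could in principle break the $R^2$ identity (each
  run has its own MST), so the invariant is only claimed per run.

`ranking_agreement()` compares the orderings induced by each metric
pair: identical or not, plus the number of pairwise inversions (the
unnormalized Kendall distance). On the hepatitis-like preset the
characteristic split emerges: $R^2$/MSE/RMSE form one camp and the
relative-error rates another, disagreeing about the non-forest models.

## Problem sizes and determinism

Everything is a pure function of (configuration, seed): dataset
generation, missingness, splits, and stochastic learners all restore
the caller's RNG state. The test suite runs the full 3125-point UC5
enumeration against a naive-loop oracle, 1000-series identity checks,
and a 100-run repeated-holdout invariant sweep on the 615-sample
preset with a 25-tree forest — sizes chosen so the whole suite
completes in well under a minute while still exercising every claimed
property at meaningful scale. The acceptance script's quantities are
desk-scale and exact; none depends on the seed it accepts.

## Known limitations

* The synthetic features are independent Gaussians per class; no
  attempt is made to model real EHR covariates, so pipeline outputs on
  presets are structural analogues, not reproductions, of results on
  the real cohorts.
* Column-mean imputation understates between-feature structure by
  construction.
* Adjusted $R^2$, partial determination, and robust losses (Huber,
  LogCosh, quantile) are out of scope, as are confidence intervals on
  metric values.
* The loess trend often drawn over the UC5 scatter is a plotting
  concern; the package emits the scatter data only.
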