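# regeval

Tools for comparing the informativeness of regression evaluation
metrics.

## The problem

When a regression model is scored on held-out data, the choice of
evaluation rate is not innocuous: different rates can rank the same set
of competing models differently. `regeval` implements seven rates with
fully specified degenerate-input semantics and the constructions that
expose their disagreements, for anyone who needs to choose — or defend —
a regression metric:

- **R²** (coefficient of determination):
  `R² = 1 − Σᵢ(Xᵢ − Yᵢ)² / Σᵢ(Yᵢ − Ȳ)²` for predictions `Xᵢ` of actual
  values `Yᵢ`; at most 1, zero for the trivial mean predictor, unbounded
  below. Undefined (an error) when the actual vector is constant.
- **MSE**, **RMSE**, **MAE** — the usual squared/absolute error means,
  in `[0, ∞)`.
- **MAPE** — `mean(|Yᵢ − Xᵢ| / |Yᵢ|)`; undefined when any `Yᵢ = 0`
  (an error from `mape()`, a flagged `NA` in the full report).
- **SMAPE** — `mean(|Xᵢ − Yᵢ| / ((|Xᵢ| + |Yᵢ|)/2))`, bounded in
  `[0, 2]` (0–200%); reaches 2 exactly when truth and prediction always
  have opposite signs. The exact-match term at `Xᵢ = Yᵢ = 0` counts as 0.
- **cnSMAPE** — the complementary normalized SMAPE,
  `1 − SMAPE/2`, in `[0, 1]` with 1 = perfect, so it is directly
  comparable with R².

On top of the metrics the package ships:

- five constructed **use cases** (`build_uc1()` … `enumerate_uc5()`,
  plus two printed-digit worked examples) in which R² and cnSMAPE give
  discordant verdicts — e.g. a prediction of `(1,2,3,4,5)` by
  `(1,2,3,5,2)` scores R² = 0 but cnSMAPE = 0.89;
- a **synthetic scenario generator** (`scenario_preset()`,
  `generate_dataset()`) producing EHR-like regression datasets with an
  ordinal target — presets mirror a 615-record hepatitis-C staging
  cohort (4 imbalanced levels, some missingness) and a 2111-record
  obesity cohort (7 balanced levels);
- a **repeated-holdout pipeline** (`run_repeated()`) that shuffles,
  splits 80/20, fits several regressors (linear model, regression tree,
  random forest by default), scores every rate on the test fold,
  averages over runs, and reports the model ranking each metric induces
  together with their pairwise agreement (`ranking_agreement()`).

## Worked example

```r
library(regeval)

# the near-constant series: truth (1,1,1,1,1,2,3), prediction all 1
evaluate_all(build_uc4())
#> Metric report on 7 points (Ybar = 1.42857, MST = 0.530612)
#>   r_squared  -0.346154
#>   mse         0.714286
#>   rmse        0.845154
#>   mae         0.428571
#>   mape        0.166667
#>   smape       0.238095
#>   cn_smape    0.880952
```

R² is negative — the prediction is worse than always guessing the mean —
while cnSMAPE claims the regression is 88.1% correct: the two rates
disagree about the same seven numbers, which is the phenomenon the
package exists to dissect.

```r
cfg <- scenario_preset("hepatitis-like", seed = 1)
rt  <- run_repeated(cfg, default_models(forest_trees = 50L), n_runs = 20)
rt
#> Repeated-holdout ranking table (20 runs, 3 methods)
#>
#> Mean metric values:
#>        r_squared   mse  rmse   mae  mape smape cn_smape
#> linear     0.874 0.069 0.262 0.209 0.187 0.188    0.906
#> tree       0.703 0.163 0.401 0.147 0.089 0.084    0.958
#> forest     0.918 0.045 0.211 0.088 0.055 0.054    0.973
#>
#> Rankings (best first):
#>     r_squared mse    rmse   mae    mape   smape  cn_smape
#> 1st forest    forest forest forest forest forest forest
#> 2nd linear    linear linear tree   tree   tree   tree
#> 3rd tree      tree   tree   linear linear linear linear
```

All seven rates crown the forest, but R²/MSE/RMSE place the linear model
second while MAE/MAPE/SMAPE prefer the tree — on identical predictions.
`summary(rt)` tabulates which metric pairs agree and counts their
pairwise ranking inversions; within any single run the R², MSE and RMSE
orderings provably coincide.

`run_command()` drives the same computations from one call and writes
deterministic CSV artifacts plus a manifest, e.g.
`run_command("uc1", output_dir = "out")` for the 16-row zeroed-line
table, or `run_command("verify")` to recompute every desk-scale check
and print pass/fail.

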