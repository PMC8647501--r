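# dyncal — dynamic updating strategies for clinical prediction models

Clinical prediction models drift: the populations they score change, and a
model developed once on a fixed derivation cohort gradually loses
calibration. `dyncal` is for biostatisticians and registry analysts who want
to quantify what *would have happened* had a deployed logistic prediction
model been updated on a schedule — and which update strategy to use.

The package implements the sequential **test-then-update** design over
incident quarter-cohorts: patients are grouped by their calendar quarter of
entry, each quarter-cohort is first scored by the currently deployed model
and only afterwards used to update it. Five strategies are compared:

| strategy | parameters re-estimated per update |
|---|---|
| never update | 0 |
| closed testing (selects among the candidates below) | data-driven |
| always recalibrate the intercept | 1 |
| always recalibrate the intercept and slope | 2 |
| always refit (model revision) | p + 1 |

A deployed model is a coefficient vector plus a chain of affine
recalibration maps on the linear predictor,
`logit p = a + b (β₀ + βᵀx)`, so intercept recalibration appends `(â, 1)`,
intercept+slope recalibration appends `(â, b̂)` (the two-parameter logistic
calibration), and a refit replaces the coefficients outright. The closed
testing procedure compares the nested candidate chain
current ⊂ +intercept ⊂ +slope ⊂ refit with likelihood-ratio tests and adopts
the simplest candidate not rejected against the largest, controlling the
familywise error of updating unnecessarily.

Update schedules are configurable: update intervals of k quarters (updates
use all data accrued since the last update) and sliding windows adding old
quarters to each update. Evaluation covers the Brier score (per quarter and
pooled), C-statistic/AUC, Hosmer–Lemeshow statistic, logistic calibration
intercept (calibration-in-the-large) and slope, per-quarter Brier
improvement versus never updating, and pairwise Wilcoxon signed-rank
comparisons between strategies (exact null distribution up to 25 quarters).

Because the registry data behind such studies are generally not shareable,
`dyncal` includes a synthetic cohort generator (`drift_scenario()`,
`generate_cohorts()`) with configurable intercept/slope drift whose default
emulates a transplant-registry structure: 12 baseline + 24 post-baseline
quarters of ~456 patients, 1-year event risk declining from ~0.178 to a
pooled ~0.132, and a 15-parameter logistic truth including a rare binary
predictor that vanishes from some small cohorts. User cohort CSVs with the
same schema (`quarter,<predictors...>,y`) plug into the same machinery.

## Worked example

```r
library(dyncal)

sc      <- default_scenario(seed = 20100101)
cohorts <- generate_cohorts(sc)            # 36 quarter-cohorts
parts   <- split_baseline(cohorts, n_baseline = 12)

never <- run_dynamic_update(parts$baseline, parts$post, update_schedule("never"))
recal <- run_dynamic_update(parts$baseline, parts$post,
                            update_schedule("recal_intercept", interval = 1))
summary(recal)
#> Strategy: recal_intercept - 24 update(s) applied
#> Pooled performance:
#>   n = 10989 (1477 events)
#>   Brier score            0.1138
#>   AUC                    0.6207
#>   Hosmer-Lemeshow        4.19 (g = 10)
#>   Calibration intercept  -0.0330
#>   Calibration slope      0.9443

summary(never)$pooled
#>   n = 10989 (1477 events)
#>   Brier score            0.1163
#>   AUC                    0.6203
#>   Hosmer-Lemeshow        180.64 (g = 10)
#>   Calibration intercept  -0.3773
#>   Calibration slope      1.0058

d <- delta_bs_series(recal, never)         # per-quarter BS difference
median(d)                                  # -0.00233  (negative = improvement)
wilcoxon_signed_rank(d)                    # p = 1.03e-05
```

Quarterly intercept recalibration tracks the drifting event rate: the pooled
Brier score drops from 0.1163 to 0.1138, the Hosmer–Lemeshow statistic
collapses from 180.6 to 4.2, and the calibration intercept moves from −0.38
to −0.03 (no average miscalibration), while discrimination (AUC) is
essentially unchanged — updating repairs calibration, not ranking. The
signed-rank test confirms the quarter-by-quarter improvement is systematic.

The full factorial comparison (strategies × intervals × windows), including
closed-testing selection tallies, pairwise Wilcoxon tables and
boxplot-ready improvement series, runs through one call:

```r
ex <- run_experiment(scenario = sc, intervals = c(1, 2, 4, 8),
                     n_baseline = 12, seed = 1)
summarize_boxplot_data(ex)$summary
write_experiment(ex, "report/")    # metrics.csv, selections.csv, pairwise.csv, ...
```

## Documentation

The methods vignette (`vignettes/dynamic-model-updating.Rmd`) documents the
model representation, the closed testing construction, schedule/window
semantics, the metric conventions, what the synthetic generator does and
does not emulate, and the simulation sizes used by the test suite.
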