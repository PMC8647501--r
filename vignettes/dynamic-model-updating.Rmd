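---
title: "Dynamic updating of clinical prediction models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic updating of clinical prediction models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncal)
```

## The problem

A clinical prediction model is typically developed once, on a fixed
derivation cohort, and then applied to future patients whose case mix and
care differ from the derivation setting. Its calibration — and sometimes its
discrimination — deteriorates over time ("calibration drift"). `dyncal`
implements the *dynamic updating* view: patients are grouped into incident
quarter-cohorts by their date of entry (e.g. date of transplant), each cohort
is first used to *test* the currently deployed model and only afterwards to
*update* it, and this test-then-update cycle repeats over the whole
post-baseline period. Because a cohort is always scored by a model that has
never seen it, no optimism correction is needed.

Five update strategies are compared:

1. **Never update** — the baseline model is used throughout.
2. **Closed testing** — at each update opportunity, a familywise-error-
   controlled selection among the candidates below (including "no update").
3. **Always recalibrate the intercept** — re-estimate a single log-odds
   shift, keeping the linear predictor as a fixed offset.
4. **Always recalibrate the intercept and slope** — the two-parameter
   logistic calibration of the current linear predictor.
5. **Always refit (model revision)** — re-estimate every coefficient.

## Model representation

A deployed model is a `pred_model`: origin coefficients
$(\beta_0, \boldsymbol\beta)$ plus an ordered chain of affine maps
$(a_i, b_i)$ on the linear predictor. The prediction for covariates $x$ is

$$\hat p(x) = \operatorname{logit}^{-1}\!\big(a + b\,(\beta_0 + \boldsymbol\beta^\top x)\big),$$

where $(a, b)$ is the algebraic collapse of the chain (composition of
$(a_1,b_1)$ then $(a_2,b_2)$ is $(a_2 + b_2 a_1,\; b_2 b_1)$). Intercept
recalibration appends $(\hat a, 1)$; intercept-and-slope recalibration
appends $(\hat a, \hat b)$; a refit replaces the origin coefficients and
empties the chain. Updates always stack on the *currently deployed* model,
not the original baseline model, so e.g. quarterly intercept recalibration
accumulates a chain that still collapses to a single shift of the baseline
linear predictor.

A practical corollary worth stating: both recalibration updates depend on
the data only through $(\mathrm{lp}, y)$ pairs, so `recalibrate_intercept()`
and `recalibrate_slope()` accept a precomputed linear predictor in place of
patient-level covariates.

## Fitting and degenerate data

All maximum-likelihood logistic fits run through IRLS
(`stats::glm.fit`, deviance tolerance `1e-12`, iteration cap 100).
Two degeneracies that sequential updating *will* encounter are handled
explicitly rather than left to crash a run:

* **Zero-variance (or aliased) columns.** Rare binary predictors can be
  absent from a small quarter-cohort. A refit drops such columns from
  estimation, records them in `dropped_columns`, and sets their coefficient
  to exactly 0. The count of parameters re-estimated reflects the effective
  model. A small ridge penalty was considered and rejected: it would
  sacrifice exact maximum-likelihood semantics, which the test oracles rely
  on.
* **Separation.** A separated fit is reported as `converged = FALSE` (the
  iteration-cap estimate is kept; no exception). The engine logs a failed
  update and retains the incumbent model; the closed testing procedure
  excludes a non-converged refit candidate from its family and proceeds on
  the remaining nesting.

## Closed testing

At an update opportunity with window data $(X, y)$ the candidates form a
nested chain: current model (0 free parameters) $\subset$ intercept
recalibration (1) $\subset$ intercept+slope recalibration (2) $\subset$
refit ($p+1$, dropped columns excluded). Every intersection hypothesis is
tested by the likelihood-ratio statistic of the largest candidate against
the hypothesis's model, which for a nested chain reduces to the standard
sequential shortcut: test refit vs current; if not rejected, keep the
current model (coherence — no simpler comparison may then force an update);
otherwise test refit vs intercept recalibration, and so on. The first
non-rejected candidate is adopted. `alpha` defaults to 0.05 and is a
configuration knob. Note the statistic for "refit vs current" tests a
*simple* hypothesis (the current model is fully specified), so its reference
distribution is $\chi^2$ with as many degrees of freedom as the refit
estimates.

One reading had to be fixed where the sequential setting is ambiguous:
candidates are compared to the **currently deployed** model at each
opportunity (updates stack), not to the original baseline model.

## Schedules, windows and evaluation timing

`update_schedule(strategy, interval = k, window_old = w)` places update
opportunities after quarters $k-1, 2k-1, \dots$ (so 24 post-baseline
quarters give $\lfloor 24/k\rfloor$ = 24, 12, 6, 3 opportunities at
$k = 1, 2, 4, 8$). Each update uses the $k$ newest quarters — all data
accrued since the last opportunity — plus `window_old` preceding quarters.
Two boundary rules:

* Old-data windows never reach into the baseline pool; they are clipped at
  the first post-baseline quarter (and the clipping is logged).
* Predictions are made **every** quarter by the deployed model regardless of
  $k$; only updating is less frequent. Pooled metrics over all post-baseline
  quarters are only meaningful under quarterly testing, which fixes this
  otherwise open reading.

The run log (`update_run`) records one prediction row per patient (each
patient predicted exactly once, by a model that never saw them) and one
event row per update opportunity.

## Performance measures

* **Brier score** `mean((p - y)^2)`, per quarter and pooled; the pooled
  score is the cohort-size-weighted mean of per-quarter scores.
* **C-statistic / AUC** via the rank-sum form, ties counted 1/2.
* **Hosmer–Lemeshow** over `g = 10` probability deciles by default
  (quantile binning, ties to the lower group); groups with zero expected
  events or non-events are collapsed into a neighbour and the effective
  group count reported.
* **Logistic calibration**: the slope is the free two-parameter fit
  $\operatorname{logit} P(y{=}1) = \alpha + \beta\,\operatorname{logit} p$;
  the reported intercept is calibration-in-the-large ($\alpha$ with
  $\beta \equiv 1$, offset fit). Both conventions are exposed.
  Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before the logit and
  clipping is counted.
* **Improvement series**: per-quarter Brier difference versus never
  updating; negative is better. Pairs of strategies are compared by
  two-sided Wilcoxon signed-rank tests on the per-quarter differences —
  exact null distribution up to $n = 25$ nonzero differences without ties
  (covering a 24-quarter horizon), normal approximation with continuity and
  tie correction beyond. All-zero difference vectors return $p = 1$ by
  convention.
* **Parameter accounting**: per-update parameter costs are 0 / 1 / 2 /
  $p{+}1$; for closed testing the per-update average is the
  selection-count-weighted mean of candidate costs
  (`weighted_param_average()`).

## The synthetic cohort generator

Registry data behind studies of this design are typically not shareable, so
`dyncal` ships a generator whose *structure* mirrors such data. A
`drift_scenario` holds the generative logistic truth: per patient in quarter
$q$,

$$\operatorname{logit} P(y{=}1 \mid x) =
  \big(\beta_0 + d_I(q)\big) + d_S(q)\,\boldsymbol\beta^\top x .$$

The default scenario (`default_scenario()`) emulates a lung-transplant-like
registry: 36 quarters (12 baseline + 24 post-baseline) of on average 456
patients (cohort sizes Poisson unless `fixed_size = TRUE`, mirroring the
quarter-to-quarter variation registries show); six continuous predictors
(age, cardiac index, BMI, creatinine, six-minute-walk distance, oxygen
need), three binary (continuous mechanical ventilation, a *rare*
creatinine-increase flag at prevalence 0.003, bilateral transplant), and two
categoricals (diagnosis group with 4 levels, functional status with 3),
reference-coded to 14 columns — a 15-parameter model. Slope magnitudes are
plausible values chosen for the emulation, not estimates from any restricted
data set. The intercept (−2.640) and default linear intercept drift
(−0.0205 log-odds/quarter) were calibrated once, by Monte-Carlo integration
over the covariate law, so that the baseline-period risk is ≈ 0.178 and the
pooled post-baseline risk ≈ 0.132, declining over time. The rare flag's
prevalence makes roughly a quarter of 456-patient cohorts carry a
zero-variance column, exercising the degenerate-refit machinery.

Per-quarter random streams are derived deterministically from the scenario
seed, so extending the horizon never perturbs earlier cohorts, and identical
seeds give bitwise-identical cohorts. An optional correlation matrix couples
the continuous predictors; the default is independence, because the real
correlation structure of such registries is not public — one of several
features of real data the generator does **not** emulate. Others: covariate
distributions shift only through the configured drift functions (no
seasonality, no policy shocks), outcomes are conditionally independent given
covariates, and there is no missingness. Passing tests on these cohorts
demonstrates the *mechanics* (scheduling, windows, leakage-free evaluation,
selection behaviour) and the *statistical properties that are
design-independent* (FWER control, oracle agreement); it does not certify
performance magnitudes on any particular registry.

## Simulation sizes used by the test suite

The suite's statistical checks use sizes chosen to make the assertions
sharp rather than exhaustive:

* Type-I behaviour of closed testing: 2000 null replicates at $n = 500$
  against the bound $0.05 + 3\sqrt{0.05\cdot 0.95/2000}$. The null design is
  a compact 6-parameter scenario (≈ 17 events per parameter at $n = 500$),
  chosen so that the $\chi^2$ asymptotics the familywise guarantee presumes
  actually hold at the simulated size; at 15 parameters and ~65 events the
  likelihood-ratio test's small-sample inflation would dominate and the
  check would measure the wrong thing.
* Power direction: 100 replicates at $n = 2000$ with a +1.0 log-odds
  intercept shift — intercept recalibration should be the modal selection.
* Drift benefit: an intercept-drift scenario losing 0.0625 log-odds per
  quarter (≈ 1.5 over a 24-quarter horizon) at 500 patients/quarter for the
  100-replicate pooled-Brier comparison, and one 2000-patient/quarter
  sequence for the per-quarter improvement medians of all four updating
  strategies.

## A worked run

```{r example, eval = FALSE}
sc <- default_scenario(seed = 20100101)
cohorts <- generate_cohorts(sc)
parts <- split_baseline(cohorts, n_baseline = 12)

run <- run_dynamic_update(parts$baseline, parts$post,
                          update_schedule("recal_intercept", interval = 1))
summary(run)

ex <- run_experiment(scenario = sc, intervals = c(1, 2, 4, 8),
                     n_baseline = 12, seed = 1)
summarize_boxplot_data(ex)$summary
plot(ex)
```

## Known limitations

* Fixed-horizon binary outcomes only; no survival-time modelling and no
  non-logistic links.
* No shrinkage or penalized refitting — refits are plain MLE, which is
  exactly why they are unstable on small windows; that instability is part
  of what the framework measures.
* No multiplicity control across quarters (by design: each opportunity's
  closed test controls its own familywise error).
* The experiment runner derives data seeds per replicate (all strategies
  must see the same cohorts for paired comparisons); strategies themselves
  are deterministic given the data.
* Scenario files restrict drift to linear-in-quarter coefficients; arbitrary
  drift functions are available through the R API only.
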