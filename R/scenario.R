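#' Describe one predictor of a synthetic cohort
#'
#' Helper constructors for the `covariates` list of [drift_scenario()].
#' Continuous predictors are Gaussian, binary predictors Bernoulli, and
#' categorical predictors multinomial with the first level as reference
#' (so a categorical with L levels expands to L - 1 indicator columns).
#'
#' @param name column name (categorical levels are appended as `name_level`).
#' @param mean,sd Gaussian parameters of a continuous predictor.
#' @param prevalence Bernoulli probability of a binary predictor, in (0, 1).
#' @param rare flag a binary predictor that is allowed to have zero variance
#'   in small cohorts (e.g. prevalence well below 1%); the generator makes no
#'   attempt to guarantee both levels are present.
#' @param levels,probs category labels and their probabilities (sum to 1).
#' @return a covariate descriptor (list) for use in [drift_scenario()].
#' @export
covariate_continuous <- function(name, mean, sd) {
  stopifnot(is.character(name), length(name) == 1L, sd > 0)
  structure(list(name = name, type = "continuous", mean = mean, sd = sd),
            class = "covariate_spec")
}

#' @rdname covariate_continuous
#' @export
covariate_binary <- function(name, prevalence, rare = FALSE) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  structure(list(name = name, type = "binary", prevalence = prevalence,
                 rare = isTRUE(rare)),
            class = "covariate_spec")
}

#' @rdname covariate_continuous
#' @export
covariate_categorical <- function(name, levels, probs) {
  stopifnot(length(levels) == length(probs), length(levels) >= 2L)
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-8)
    stop("level probabilities must be positive and sum to 1", call. = FALSE)
  structure(list(name = name, type = "categorical",
                 levels = as.character(levels), probs = as.numeric(probs)),
            class = "covariate_spec")
}

# expanded (reference-coded) column names for one descriptor
expanded_names <- function(cv) {
  switch(cv$type,
         continuous = cv$name,
         binary     = cv$name,
         categorical = paste(cv$name, cv$levels[-1L], sep = "_"))
}

#' Generative truth for a sequence of drifting quarter-cohorts
#'
#' A drift scenario holds the data-generating logistic model for incident
#' quarter-cohorts: baseline coefficients plus per-quarter drift in the
#' intercept (additive, log-odds) and slopes (multiplicative). Each patient in
#' quarter `q` has outcome probability
#' `plogis((baseline_intercept + intercept_drift(q)) + slope_drift(q) * (x %*% baseline_slopes))`.
#'
#' @param n_quarters number of quarter-cohorts to generate.
#' @param n_per_quarter mean cohort size; sizes are Poisson around this value
#'   unless `fixed_size = TRUE`.
#' @param baseline_intercept log-odds intercept at quarter 0 before drift.
#' @param baseline_slopes named vector of log-odds-per-unit coefficients, one
#'   per expanded predictor column (categoricals reference-coded).
#' @param covariates list of descriptors from [covariate_continuous()],
#'   [covariate_binary()], [covariate_categorical()].
#' @param intercept_drift function of quarter index (0-based) returning an
#'   additive log-odds shift; default no drift.
#' @param slope_drift function of quarter index returning a multiplicative
#'   factor applied to all slopes; default 1.
#' @param fixed_size if TRUE every cohort has exactly `n_per_quarter` rows
#'   (deterministic bookkeeping for tests).
#' @param correlation optional correlation matrix for the continuous
#'   predictors (in their order of appearance); default independence.
#' @param seed integer master seed; per-quarter streams are derived from it so
#'   extending `n_quarters` never perturbs earlier cohorts.
#' @return an object of class `drift_scenario`.
#' @seealso [generate_cohorts()], [default_scenario()]
#' @export
drift_scenario <- function(n_quarters, n_per_quarter,
                           baseline_intercept, baseline_slopes,
                           covariates,
                           intercept_drift = function(q) 0,
                           slope_drift = function(q) 1,
                           fixed_size = FALSE,
                           correlation = NULL,
                           seed = 1L) {
  if (n_quarters < 1 || n_per_quarter < 1)
    stop("invalid scenario: n_quarters and n_per_quarter must be positive",
         call. = FALSE)
  stopifnot(is.list(covariates), length(covariates) >= 1L,
            is.function(intercept_drift), is.function(slope_drift))
  cols <- unlist(lapply(covariates, expanded_names))
  if (anyDuplicated(cols))
    stop("duplicated expanded column names in covariates", call. = FALSE)
  if (length(baseline_slopes) != length(cols))
    stop(sprintf("baseline_slopes has length %d but covariates expand to %d columns",
                 length(baseline_slopes), length(cols)), call. = FALSE)
  baseline_slopes <- stats::setNames(as.numeric(baseline_slopes), cols)
  n_cont <- sum(vapply(covariates, function(v) v$type == "continuous", logical(1)))
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) || nrow(correlation) != n_cont ||
        ncol(correlation) != n_cont)
      stop("correlation must be a square matrix over the continuous predictors",
           call. = FALSE)
    if (any(abs(correlation - t(correlation)) > 1e-10) ||
        any(abs(diag(correlation) - 1) > 1e-10))
      stop("correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  structure(list(
    n_quarters = as.integer(n_quarters),
    n_per_quarter = n_per_quarter,
    baseline_intercept = baseline_intercept,
    baseline_slopes = baseline_slopes,
    covariates = covariates,
    intercept_drift = intercept_drift,
    slope_drift = slope_drift,
    fixed_size = isTRUE(fixed_size),
    correlation = correlation,
    seed = as.integer(seed),
    columns = cols
  ), class = "drift_scenario")
}

#' @export
print.drift_scenario <- function(x, ...) {
  cat("Drift scenario:", x$n_quarters, "quarter-cohorts, ~",
      x$n_per_quarter, "patients/quarter\n")
  cat("  predictors:", length(x$covariates), "covariates ->",
      length(x$columns), "expanded columns (",
      length(x$columns) + 1L, "model parameters )\n")
  cat("  baseline intercept:", format(x$baseline_intercept), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Default registry-like drift scenario
#'
#' A scenario emulating the statistical structure of a national transplant
#' registry split into quarterly incident cohorts: 36 quarters (12 baseline +
#' 24 post-baseline) of on average 456 adult recipients, a 1-year mortality
#' risk near 0.18 in the baseline period drifting down to a pooled 0.13
#' post-baseline, and a predictor mix patterned on the covariates of a
#' post-transplant survival score (continuous age, cardiac index, BMI,
#' creatinine, six-minute-walk distance and oxygen need; binary continuous
#' mechanical ventilation, a rare creatinine-increase flag and bilateral
#' transplant; diagnosis group with 4 levels and functional status with 3).
#' The 14 expanded columns give a 15-parameter logistic model. Slope and
#' distribution values are plausible magnitudes, not estimates from any
#' restricted data set.
#'
#' @param n_quarters,n_per_quarter,seed overrides of the default sizes.
#' @param intercept_drift_per_quarter additive log-odds drift per quarter
#'   (negative = declining risk); the default -0.0205 reproduces the decline
#'   from ~0.178 (baseline period) to a pooled ~0.132 post-baseline.
#' @param slope_drift_per_quarter multiplicative slope drift per quarter
#'   (slope factor is `1 + q * slope_drift_per_quarter`); default 0.
#' @param fixed_size passed to [drift_scenario()].
#' @return a `drift_scenario`.
#' @export
default_scenario <- function(n_quarters = 36L, n_per_quarter = 456,
                             seed = 20100101L,
                             intercept_drift_per_quarter = -0.0205,
                             slope_drift_per_quarter = 0,
                             fixed_size = FALSE) {
  covs <- list(
    covariate_continuous("age", 55, 12),
    covariate_continuous("cardiac_index", 2.8, 0.8),
    covariate_continuous("bmi", 25, 4.5),
    covariate_continuous("creatinine", 1.0, 0.35),
    covariate_continuous("six_min_walk", 750, 300),
    covariate_continuous("o2_rest", 2.5, 2.0),
    covariate_binary("mech_vent", 0.06),
    covariate_binary("creat_increase", 0.003, rare = TRUE),
    covariate_binary("bilateral", 0.65),
    covariate_categorical("diagnosis_group", c("A", "B", "C", "D"),
                          c(0.35, 0.10, 0.10, 0.45)),
    covariate_categorical("functional_status", c("1", "2", "3"),
                          c(0.15, 0.70, 0.15))
  )
  slopes <- c(
    age = 0.02, cardiac_index = -0.20, bmi = 0.015, creatinine = 0.35,
    six_min_walk = -6e-04, o2_rest = 0.06,
    mech_vent = 0.55, creat_increase = 0.40, bilateral = -0.25,
    diagnosis_group_B = 0.15, diagnosis_group_C = 0.35, diagnosis_group_D = 0.25,
    functional_status_2 = 0.15, functional_status_3 = 0.35
  )
  di <- intercept_drift_per_quarter
  ds <- slope_drift_per_quarter
  drift_scenario(
    n_quarters = n_quarters, n_per_quarter = n_per_quarter,
    baseline_intercept = -2.640,
    baseline_slopes = slopes, covariates = covs,
    intercept_drift = function(q) di * q,
    slope_drift = function(q) 1 + ds * q,
    fixed_size = fixed_size, seed = seed
  )
}

#' Read or write a drift scenario as a flat configuration file
#'
#' Scenario files are flat key-value documents (JSON, or YAML when the `yaml`
#' package is available) mirroring the [drift_scenario()] fields. Because the
#' file format is flat, drift must be linear: the keys
#' `intercept_drift_per_quarter` and `slope_drift_per_quarter` are stored in
#' place of the drift functions.
#'
#' @param scenario a `drift_scenario` with linear drift.
#' @param path file path; `.yml`/`.yaml` selects YAML, anything else JSON.
#' @return `read_scenario` returns a `drift_scenario`; `write_scenario`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  di <- scenario$intercept_drift
  ds <- scenario$slope_drift
  qs <- 0:max(1L, scenario$n_quarters - 1L)
  d_i <- vapply(qs, di, numeric(1))
  d_s <- vapply(qs, ds, numeric(1))
  lin <- function(v, q) {
    if (length(q) < 2L) return(0)
    fit <- stats::lm.fit(cbind(1, q), v)
    if (max(abs(fit$residuals)) > 1e-8)
      stop("only linear drift can be serialized to a flat scenario file",
           call. = FALSE)
    fit$coefficients[2L]
  }
  obj <- list(
    n_quarters = scenario$n_quarters,
    n_per_quarter = scenario$n_per_quarter,
    baseline_intercept = scenario$baseline_intercept,
    baseline_slopes = as.list(scenario$baseline_slopes),
    intercept_drift_per_quarter = unname(lin(d_i, qs)),
    slope_drift_per_quarter = unname(lin(d_s - 1, qs)),
    fixed_size = scenario$fixed_size,
    seed = scenario$seed,
    covariates = lapply(scenario$covariates, unclass)
  )
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML scenario files", call. = FALSE)
    writeLines(yaml::as.yaml(obj), path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML scenario files", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  covs <- lapply(obj$covariates, function(cv) {
    switch(cv$type,
           continuous = covariate_continuous(cv$name, cv$mean, cv$sd),
           binary = covariate_binary(cv$name, cv$prevalence, isTRUE(cv$rare)),
           categorical = covariate_categorical(cv$name, unlist(cv$levels),
                                               unlist(cv$probs)),
           stop("unknown covariate type: ", cv$type, call. = FALSE))
  })
  di <- as.numeric(obj$intercept_drift_per_quarter %||% 0)
  ds <- as.numeric(obj$slope_drift_per_quarter %||% 0)
  drift_scenario(
    n_quarters = obj$n_quarters,
    n_per_quarter = obj$n_per_quarter,
    baseline_intercept = obj$baseline_intercept,
    baseline_slopes = unlist(obj$baseline_slopes),
    covariates = covs,
    intercept_drift = function(q) di * q,
    slope_drift = function(q) 1 + ds * q,
    fixed_size = isTRUE(obj$fixed_size),
    seed = obj$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
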