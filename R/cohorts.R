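#' Construct a quarter-cohort
#'
#' One incident cohort: all patients entering in a given calendar quarter,
#' followed for the fixed outcome horizon. Membership is by quarter of origin
#' only.
#'
#' @param quarter 0-based quarter index.
#' @param X numeric predictor matrix (rows = patients, columns = expanded
#'   predictors).
#' @param y binary outcome vector (1 = event within the horizon).
#' @return an object of class `quarter_cohort`.
#' @export
quarter_cohort <- function(quarter, X, y) {
  X <- as.matrix(X)
  check_binary_outcome(y)
  if (nrow(X) != length(y))
    stop("X and y disagree on the number of patients", call. = FALSE)
  structure(list(quarter = as.integer(quarter), X = X, y = as.numeric(y)),
            class = "quarter_cohort")
}

#' @export
print.quarter_cohort <- function(x, ...) {
  cat(sprintf("Quarter-cohort q=%d: %d patients, %d events (risk %.3f)\n",
              x$quarter, length(x$y), sum(x$y), mean(x$y)))
  invisible(x)
}

# draw the expanded predictor matrix for one cohort under a scenario
draw_predictors <- function(scenario, n) {
  cols <- scenario$columns
  X <- matrix(0, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  cont <- Filter(function(v) v$type == "continuous", scenario$covariates)
  if (length(cont)) {
    Z <- matrix(stats::rnorm(n * length(cont)), nrow = n)
    if (!is.null(scenario$correlation)) {
      L <- chol(scenario$correlation)
      Z <- Z %*% L
    }
    for (j in seq_along(cont))
      X[, cont[[j]]$name] <- cont[[j]]$mean + cont[[j]]$sd * Z[, j]
  }
  for (cv in scenario$covariates) {
    if (cv$type == "binary") {
      X[, cv$name] <- stats::rbinom(n, 1, cv$prevalence)
    } else if (cv$type == "categorical") {
      lev <- sample(cv$levels, n, replace = TRUE, prob = cv$probs)
      for (l in cv$levels[-1L])
        X[, paste(cv$name, l, sep = "_")] <- as.numeric(lev == l)
    }
  }
  X
}

#' Generate a sequence of drifting incident quarter-cohorts
#'
#' Draws `scenario$n_quarters` cohorts. For each patient in quarter `q` the
#' outcome is Bernoulli with
#' `logit(p) = (b0 + intercept_drift(q)) + slope_drift(q) * (x %*% slopes)`.
#' Each quarter uses a random stream derived deterministically from the
#' scenario seed, so regenerating with more quarters leaves earlier cohorts
#' untouched, and identical seeds give bitwise-identical output.
#'
#' @param scenario a [drift_scenario()].
#' @return list of [quarter_cohort()] objects, quarters `0 .. n_quarters - 1`.
#' @export
generate_cohorts <- function(scenario) {
  if (!inherits(scenario, "drift_scenario"))
    stop("scenario must be a drift_scenario", call. = FALSE)
  lapply(seq_len(scenario$n_quarters) - 1L, function(q) {
    with_seed(derive_seed(scenario$seed, q), {
      n <- if (scenario$fixed_size) as.integer(round(scenario$n_per_quarter))
           else stats::rpois(1L, scenario$n_per_quarter)
      n <- max(n, 1L)
      X <- draw_predictors(scenario, n)
      lp <- (scenario$baseline_intercept + scenario$intercept_drift(q)) +
        scenario$slope_drift(q) * drop(X %*% scenario$baseline_slopes)
      y <- stats::rbinom(n, 1L, expit(lp))
      quarter_cohort(q, X, y)
    })
  })
}

#' Split cohorts into a pooled baseline period and post-baseline quarters
#'
#' The first `n_baseline` cohorts are row-concatenated into a single baseline
#' pool (used to fit the original prediction model); the remaining cohorts are
#' returned in order and re-indexed from quarter 0 (the first post-baseline
#' quarter).
#'
#' @param cohorts list of `quarter_cohort`.
#' @param n_baseline number of leading cohorts pooled as baseline.
#' @return list with elements `baseline` (list `X`, `y`; `NULL` when
#'   `n_baseline = 0`) and `post` (list of `quarter_cohort`, re-indexed).
#' @export
split_baseline <- function(cohorts, n_baseline) {
  if (n_baseline >= length(cohorts))
    stop("n_baseline must be smaller than the number of cohorts", call. = FALSE)
  if (n_baseline < 0) stop("n_baseline must be non-negative", call. = FALSE)
  base <- NULL
  if (n_baseline > 0) {
    head_c <- cohorts[seq_len(n_baseline)]
    base <- list(
      X = do.call(rbind, lapply(head_c, `[[`, "X")),
      y = unlist(lapply(head_c, `[[`, "y"), use.names = FALSE)
    )
  }
  post <- cohorts[setdiff(seq_along(cohorts), seq_len(n_baseline))]
  post <- lapply(seq_along(post), function(i) {
    ch <- post[[i]]
    ch$quarter <- i - 1L
    ch
  })
  list(baseline = base, post = post)
}

#' Per-quarter cohort bookkeeping
#'
#' @param cohorts list of `quarter_cohort`.
#' @return data frame with one row per quarter: `quarter`, `n`, `events`,
#'   `risk`.
#' @export
cohort_summary <- function(cohorts) {
  data.frame(
    quarter = vapply(cohorts, `[[`, integer(1), "quarter"),
    n = vapply(cohorts, function(c) length(c$y), integer(1)),
    events = vapply(cohorts, function(c) as.integer(sum(c$y)), integer(1)),
    risk = vapply(cohorts, function(c) mean(c$y), numeric(1))
  )
}

#' Event risk from event and patient counts
#'
#' The observed outcome risk of a (pooled) cohort, `events / n`, as printed in
#' registry summaries.
#'
#' @param events number of events.
#' @param n number of patients.
#' @param digits rounding used for display conventions (default 3).
#' @return the risk, rounded to `digits`.
#' @export
event_risk <- function(events, n, digits = 3) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  round(events / n, digits)
}

#' Read and write quarter-cohort tables
#'
#' Cohort files are plain CSV with a mandatory header, columns
#' `quarter,<predictor...>,y`, and no missing values. `write_cohorts` emits
#' one file for a whole sequence; `read_cohorts` reconstructs the ordered
#' cohort list.
#'
#' @param cohorts list of `quarter_cohort`.
#' @param path CSV file path.
#' @return `read_cohorts` returns a list of `quarter_cohort`; `write_cohorts`
#'   returns `path` invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  tabs <- lapply(cohorts, function(ch) {
    data.frame(quarter = ch$quarter, as.data.frame(ch$X), y = ch$y,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohorts
#' @export
read_cohorts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("quarter", "y")
  if (!all(need %in% names(df)))
    stop("cohort file must have 'quarter' and 'y' columns", call. = FALSE)
  if (anyNA(df)) stop("cohort file contains missing values", call. = FALSE)
  pred <- setdiff(names(df), need)
  qs <- sort(unique(df$quarter))
  lapply(qs, function(q) {
    sub <- df[df$quarter == q, , drop = FALSE]
    Xm <- as.matrix(sub[, pred, drop = FALSE])
    rownames(Xm) <- NULL
    quarter_cohort(q, Xm, sub$y)
  })
}
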