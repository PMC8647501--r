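#' Closed testing selection among candidate model updates
#'
#' At an update opportunity the candidate updates form a nested chain:
#' current model (0 free parameters) < intercept recalibration (1) <
#' intercept-and-slope recalibration (2) < full refit (p + 1). Each
#' intersection hypothesis is tested by the likelihood-ratio test of the
#' largest candidate against the hypothesis's model (2 * difference in
#' log-likelihood, df = difference in free parameters), and the closed
#' testing principle reduces to sequential testing along the chain: the
#' selected update is the simplest candidate NOT rejected against the largest
#' model, and a candidate can only be adopted once every simpler hypothesis
#' has been rejected at `alpha`. This controls the familywise error of
#' adopting any unnecessary update at `alpha`.
#'
#' A non-converged refit candidate (e.g. separation in a small cohort) is
#' excluded from the family and the procedure runs on the remaining nesting;
#' the exclusion is recorded in the decision.
#'
#' @param current the deployed `pred_model`.
#' @param X,y update-window data.
#' @param alpha familywise significance level in (0, 1); default 0.05.
#' @return list with elements `decision` (class `closed_test_decision`:
#'   `selected`, `tests` data frame, `alpha`, `n_parameters_reestimated`,
#'   `excluded`) and `model` (the adopted `pred_model`; the input unchanged
#'   when `selected = "no_update"`).
#' @export
closed_test_select <- function(current, X, y, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  X <- as.matrix(X)
  check_binary_outcome(y)
  if (all(y == 1) || all(y == 0))
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)

  lp <- linear_predictor(current, X)
  ll0 <- model_loglik(current, X, y)

  fits <- list(no_update = list(loglik = ll0, df = 0L, fit = NULL))
  excluded <- character()

  f_int <- recalibrate_intercept(current, y = y, lp = lp)
  fits$recal_intercept <- list(loglik = f_int$log_likelihood, df = 1L, fit = f_int)

  if (length(unique(lp)) > 1L) {
    f_slp <- recalibrate_slope(current, y = y, lp = lp)
    fits$recal_slope <- list(loglik = f_slp$log_likelihood, df = 2L, fit = f_slp)
  } else {
    excluded <- c(excluded, "recal_slope")
  }

  f_ref <- fit_logistic(X, y, provenance = current$provenance)
  if (f_ref$converged) {
    fits$refit <- list(loglik = f_ref$log_likelihood,
                       df = f_ref$n_parameters_reestimated, fit = f_ref)
  } else {
    excluded <- c(excluded, "refit")
  }

  cand <- names(fits)
  top <- cand[length(cand)]
  ll_top <- fits[[top]]$loglik
  df_top <- fits[[top]]$df

  tests <- data.frame(comparison = character(), statistic = numeric(),
                      df = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  selected <- top
  for (cd in cand[-length(cand)]) {
    stat <- max(0, 2 * (ll_top - fits[[cd]]$loglik))
    df <- df_top - fits[[cd]]$df
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    tests <- rbind(tests, data.frame(
      comparison = paste0(top, "_vs_", cd),
      statistic = stat, df = df, p_value = p, stringsAsFactors = FALSE))
    if (p >= alpha) { selected <- cd; break }
  }

  n_reest <- if (selected == "no_update") 0L else
    fits[[selected]]$fit$n_parameters_reestimated
  model <- if (selected == "no_update") current else fits[[selected]]$fit$model
  decision <- structure(list(selected = selected, tests = tests,
                             alpha = alpha,
                             n_parameters_reestimated = n_reest,
                             excluded = excluded),
                        class = "closed_test_decision")
  list(decision = decision, model = model)
}

#' @export
print.closed_test_decision <- function(x, ...) {
  cat("Closed testing decision: selected", x$selected,
      sprintf("(alpha = %g, %d parameter(s) re-estimated)\n",
              x$alpha, x$n_parameters_reestimated))
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  if (length(x$excluded))
    cat("  excluded candidates:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Tally candidate selections across closed testing decisions
#'
#' @param decisions list of `closed_test_decision` (or character vector of
#'   selections).
#' @return named integer vector over the four candidates; sums to
#'   `length(decisions)`.
#' @export
tally_selections <- function(decisions) {
  sel <- if (is.character(decisions)) decisions
         else vapply(decisions, function(d) d$selected, character(1))
  lev <- c("no_update", "recal_intercept", "recal_slope", "refit")
  tab <- table(factor(sel, levels = lev))
  stats::setNames(as.integer(tab), lev)
}
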