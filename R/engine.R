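#' Define when and how a deployed model is updated
#'
#' An update schedule fixes the strategy, the update interval `k` (quarters
#' between update opportunities; opportunities fall after quarters
#' `k-1, 2k-1, ...`, i.e. once `k` new post-baseline cohorts have accrued),
#' and the sliding window: each update uses the `k` newest quarters ("all
#' data accrued since the most recent update") plus `window_old` additional
#' preceding quarters of old data, clipped at the start of the post-baseline
#' period (old-data windows never reach into the baseline pool).
#'
#' @param strategy one of `"never"`, `"closed_testing"`, `"recal_intercept"`,
#'   `"recal_slope"`, `"refit"`.
#' @param interval update interval `k` in quarters (the study grid uses
#'   1, 2, 4, 8; any positive integer is accepted).
#' @param window_old additional preceding quarters of old data per update
#'   (the study grid uses 0, 1, 3, 7 with `interval = 1`).
#' @param alpha significance level of the closed testing procedure.
#' @return an object of class `update_schedule`.
#' @export
update_schedule <- function(strategy = c("never", "closed_testing",
                                         "recal_intercept", "recal_slope",
                                         "refit"),
                            interval = 1L, window_old = 0L, alpha = 0.05) {
  strategy <- match.arg(strategy)
  if (interval <= 0) stop("update interval must be positive", call. = FALSE)
  if (window_old < 0) stop("window_old must be non-negative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(strategy = strategy, interval = as.integer(interval),
                 window_old = as.integer(window_old), alpha = alpha),
            class = "update_schedule")
}

#' @export
print.update_schedule <- function(x, ...) {
  cat(sprintf("Update schedule: %s, every %d quarter(s), window %d new + %d old\n",
              x$strategy, x$interval, x$interval, x$window_old))
  invisible(x)
}

#' Number of update events implied by a schedule
#'
#' For the always-update strategies the number of updates over `n_quarters`
#' post-baseline quarters is fully determined by the interval:
#' `floor(n_quarters / k)`. For closed testing this is the maximum number of
#' updates (the realized count comes from the run log); for never-update it
#' is 0.
#'
#' @param schedule an [update_schedule()].
#' @param n_quarters number of post-baseline quarters.
#' @return integer count.
#' @export
count_updates <- function(schedule, n_quarters) {
  if (n_quarters < 0) stop("n_quarters must be non-negative", call. = FALSE)
  if (schedule$interval <= 0) stop("update interval must be positive", call. = FALSE)
  if (schedule$strategy == "never") return(0L)
  as.integer(n_quarters %/% schedule$interval)
}

#' Assemble the sliding-window data for an update opportunity
#'
#' Row-concatenates the last `interval + window_old` quarter-cohorts up to and
#' including quarter `q`, oldest first. Quarters before the start of the
#' post-baseline period are unavailable: the window is silently clipped and
#' the quarters actually used are reported.
#'
#' @param post_cohorts list of post-baseline `quarter_cohort` (quarter 0
#'   first).
#' @param q 0-based quarter index of the update opportunity.
#' @param schedule an [update_schedule()].
#' @return list `X`, `y`, `quarters` (indices used), `clipped` (logical).
#' @export
assemble_window <- function(post_cohorts, q, schedule) {
  want_first <- q - (schedule$interval + schedule$window_old) + 1L
  first <- max(0L, want_first)
  idx <- seq.int(first, q)
  chs <- post_cohorts[idx + 1L]
  list(X = do.call(rbind, lapply(chs, `[[`, "X")),
       y = unlist(lapply(chs, `[[`, "y"), use.names = FALSE),
       quarters = idx,
       clipped = want_first < 0L)
}

#' Run a dynamic updating strategy over a sequence of quarter-cohorts
#'
#' The sequential test-then-update engine. A baseline model is fitted to the
#' pooled baseline data and deployed. Each post-baseline quarter is first
#' predicted by the currently deployed model (so no patient's data ever
#' influence the model that predicts them); then, if the quarter closes an
#' update interval, the strategy is applied to the scheduled sliding window
#' and the updated model is deployed for subsequent quarters. Every quarter is
#' predicted regardless of the interval; only updating is less frequent.
#' A failed update (non-convergence) is logged and the incumbent model
#' retained.
#'
#' @param baseline list with `X` and `y`: the pooled baseline cohorts, or a
#'   ready-made `pred_model` to deploy as the baseline model.
#' @param post_cohorts list of post-baseline `quarter_cohort` (quarter 0
#'   first).
#' @param schedule an [update_schedule()].
#' @return an object of class `update_run` with components
#'   \describe{
#'     \item{predictions}{data frame `quarter`, `row`, `p`, `y`, `model`
#'       (provenance label of the deploying model); every post-baseline
#'       patient appears exactly once.}
#'     \item{updates}{data frame of update events: `quarter`, `candidate`
#'       (what was applied), `n_parameters`, `window_first`, `window_last`,
#'       `n_window`, `converged`, `applied`.}
#'     \item{decisions}{list of `closed_test_decision` (closed testing only).}
#'     \item{baseline_fit}{the baseline `fit_result` (or supplied model).}
#'     \item{final_model}{the model deployed after the last quarter.}
#'     \item{schedule, n_quarters}{the configuration.}
#'   }
#' @export
run_dynamic_update <- function(baseline, post_cohorts, schedule) {
  if (!inherits(schedule, "update_schedule"))
    stop("schedule must be an update_schedule", call. = FALSE)
  if (length(post_cohorts) == 0L)
    stop("no post-baseline cohorts to run on", call. = FALSE)

  if (inherits(baseline, "pred_model")) {
    baseline_fit <- NULL
    current <- baseline
  } else {
    baseline_fit <- fit_logistic(baseline$X, baseline$y,
                                 provenance = list(strategy = "baseline",
                                                   quarter = NA_integer_))
    current <- baseline_fit$model
  }
  current$provenance$label <- "baseline"

  k <- schedule$interval
  preds <- vector("list", length(post_cohorts))
  events <- list()
  decisions <- list()

  for (i in seq_along(post_cohorts)) {
    ch <- post_cohorts[[i]]
    q <- ch$quarter
    p <- predict(current, ch$X)
    preds[[i]] <- data.frame(quarter = q, row = seq_along(ch$y),
                             p = p, y = ch$y,
                             model = current$provenance$label,
                             stringsAsFactors = FALSE)

    if (schedule$strategy != "never" && (q + 1L) %% k == 0L) {
      w <- assemble_window(post_cohorts, q, schedule)
      prov <- list(strategy = schedule$strategy, quarter = q,
                   label = sprintf("%s@q%d", schedule$strategy, q))
      res <- switch(schedule$strategy,
        recal_intercept = recalibrate_intercept(current, w$X, w$y,
                                                provenance = prov),
        recal_slope = recalibrate_slope(current, w$X, w$y, provenance = prov),
        refit = refit(current, w$X, w$y, provenance = prov),
        closed_testing = {
          ct <- closed_test_select(current, w$X, w$y, alpha = schedule$alpha)
          decisions[[length(decisions) + 1L]] <- ct$decision
          m <- ct$model
          if (ct$decision$selected != "no_update") m$provenance <- prov
          fit_result(m, ct$decision$n_parameters_reestimated,
                     NA_real_, TRUE)
        })
      candidate <- if (schedule$strategy == "closed_testing")
        decisions[[length(decisions)]]$selected else schedule$strategy
      applied <- res$converged && candidate != "no_update"
      if (res$converged && candidate != "no_update") current <- res$model
      events[[length(events) + 1L]] <- data.frame(
        quarter = q, candidate = candidate,
        n_parameters = res$n_parameters_reestimated,
        window_first = w$quarters[1L],
        window_last = w$quarters[length(w$quarters)],
        n_window = length(w$y),
        converged = res$converged, applied = applied,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(
    predictions = do.call(rbind, preds),
    updates = if (length(events)) do.call(rbind, events) else
      data.frame(quarter = integer(), candidate = character(),
                 n_parameters = integer(), window_first = integer(),
                 window_last = integer(), n_window = integer(),
                 converged = logical(), applied = logical()),
    decisions = decisions,
    baseline_fit = baseline_fit,
    final_model = current,
    schedule = schedule,
    n_quarters = length(post_cohorts)
  ), class = "update_run")
}

#' Number of updates actually performed in a run
#'
#' Counts the update events at which a candidate other than "no update" was
#' successfully applied (for always-update strategies this equals
#' [count_updates()] unless an update failed to converge).
#'
#' @param run an `update_run`.
#' @return integer count.
#' @export
n_updates <- function(run) {
  sum(run$updates$applied)
}

#' @export
print.update_run <- function(x, ...) {
  cat(sprintf("Dynamic update run: %s over %d quarter(s), %d update(s) applied\n",
              x$schedule$strategy, x$n_quarters, n_updates(x)))
  invisible(x)
}

#' Evaluate an update run
#'
#' Computes the pooled metric panel across all post-baseline predictions and
#' a per-quarter panel table.
#'
#' @param object an `update_run`.
#' @param g Hosmer-Lemeshow group count.
#' @param ... unused.
#' @return list of class `summary.update_run` with `pooled` (a
#'   [metric_panel()]) and `per_quarter` (data frame).
#' @export
summary.update_run <- function(object, g = 10L, ...) {
  pr <- object$predictions
  pooled <- metric_panel(pr$p, pr$y, g = g)
  qlev <- sort(unique(pr$quarter))
  per_q <- do.call(rbind, lapply(split(pr, factor(pr$quarter, levels = qlev)),
                                 function(s) {
    pan <- tryCatch(metric_panel(s$p, s$y, g = g), error = function(e) NULL)
    data.frame(quarter = s$quarter[1L],
               n = nrow(s), n_events = sum(s$y),
               brier = brier(s$p, s$y),
               auc = if (is.null(pan)) NA_real_ else pan$auc,
               hl = if (is.null(pan)) NA_real_ else pan$hl_statistic,
               calibration_intercept = if (is.null(pan)) NA_real_ else
                 pan$calibration_intercept,
               calibration_slope = if (is.null(pan)) NA_real_ else
                 pan$calibration_slope)
  }))
  rownames(per_q) <- NULL
  structure(list(pooled = pooled, per_quarter = per_q,
                 strategy = object$schedule$strategy,
                 n_updates = n_updates(object)),
            class = "summary.update_run")
}

#' @export
print.summary.update_run <- function(x, ...) {
  cat("Strategy:", x$strategy, "-", x$n_updates, "update(s) applied\n")
  cat("Pooled performance:\n")
  print(x$pooled)
  invisible(x)
}

#' @param x an `update_run`.
#' @param ... passed to [graphics::plot()].
#' @rdname summary.update_run
#' @export
plot.update_run <- function(x, ...) {
  s <- summary(x)$per_quarter
  graphics::plot(s$quarter, s$brier, type = "b", xlab = "quarter",
                 ylab = "Brier score",
                 main = paste("Per-quarter Brier score:", x$schedule$strategy),
                 ...)
  invisible(x)
}
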