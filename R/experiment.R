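#' Run a factorial comparison of update strategies
#'
#' Orchestrates the full grid strategy x interval x sliding window over
#' synthetic cohorts generated from a scenario (or user-supplied cohorts with
#' the same schema). Within a replicate every cell runs on the SAME generated
#' cohort sequence, so pairwise Brier-score comparisons between strategies are
#' paired by quarter, as in a registry analysis. Replicate data seeds are
#' derived from the master seed by stable hashing of the replicate label, so
#' adding replicates or grid cells never changes existing results.
#'
#' @param scenario a [drift_scenario()] (ignored when `cohorts` is given).
#' @param strategies character vector of strategies (see [update_schedule()]).
#' @param intervals update intervals to cross with the strategies.
#' @param windows_old old-data window lengths to cross (each combined with
#'   every interval).
#' @param alpha closed-testing significance level.
#' @param n_baseline number of leading cohorts pooled as the baseline period.
#' @param replicates number of independent cohort sequences to simulate.
#' @param seed master seed.
#' @param cohorts optional pre-built list of `quarter_cohort` (forces
#'   `replicates = 1`).
#' @param g Hosmer-Lemeshow group count for the metric panels.
#' @return object of class `update_experiment`: \describe{
#'   \item{cells}{list of per-cell results (`run`, pooled `panel`,
#'     `delta_bs`, selection `tally`, update counts).}
#'   \item{metrics}{long data frame mirroring the tabular report layout
#'     (replicate, strategy, interval, window_old, metric, value).}
#'   \item{pairwise}{pairwise Wilcoxon table (median per-quarter Brier
#'     difference and p-value per strategy pair and cell).}
#'   \item{config}{the echoed configuration.}}
#' @export
run_experiment <- function(scenario = default_scenario(),
                           strategies = c("never", "closed_testing",
                                          "recal_intercept", "recal_slope",
                                          "refit"),
                           intervals = 1L,
                           windows_old = 0L,
                           alpha = 0.05,
                           n_baseline = 12L,
                           replicates = 1L,
                           seed = 1L,
                           cohorts = NULL,
                           g = 10L) {
  stopifnot(length(strategies) >= 1L, replicates >= 1L)
  strategies <- match.arg(strategies, c("never", "closed_testing",
                                        "recal_intercept", "recal_slope",
                                        "refit"), several.ok = TRUE)
  if (!is.null(cohorts) && replicates != 1L)
    stop("user-supplied cohorts imply a single replicate", call. = FALSE)

  cells <- list()
  metrics <- list()
  pairwise <- list()
  skipped <- list()

  for (r in seq_len(replicates)) {
    dat <- if (!is.null(cohorts)) cohorts else {
      sc <- scenario
      sc$seed <- hash_seed(seed, sprintf("replicate:%d", r))
      generate_cohorts(sc)
    }
    sp <- split_baseline(dat, n_baseline)
    nq <- length(sp$post)

    for (k in intervals) for (w in windows_old) {
      if (nq %/% k == 0L) {
        skipped[[length(skipped) + 1L]] <- sprintf(
          "replicate %d interval %d window %d: no update opportunity in %d quarters",
          r, k, w, nq)
        next
      }
      runs <- list()
      for (st in strategies) {
        sched <- update_schedule(st, interval = k, window_old = w,
                                 alpha = alpha)
        runs[[st]] <- run_dynamic_update(sp$baseline, sp$post, sched)
      }
      never_run <- if (!is.null(runs$never)) runs$never else
        run_dynamic_update(sp$baseline, sp$post,
                           update_schedule("never", interval = k,
                                           window_old = w, alpha = alpha))
      for (st in names(runs)) {
        run <- runs[[st]]
        pan <- metric_panel(run$predictions$p, run$predictions$y, g = g)
        dbs <- delta_bs_series(run, never_run)
        tally <- if (st == "closed_testing") tally_selections(run$decisions)
                 else NULL
        key <- sprintf("r%d_%s_k%d_w%d", r, st, k, w)
        cells[[key]] <- list(replicate = r, strategy = st, interval = k,
                             window_old = w, run = run, panel = pan,
                             delta_bs = dbs, tally = tally,
                             n_updates = n_updates(run),
                             max_updates = count_updates(run$schedule, nq))
        metrics[[key]] <- data.frame(
          replicate = r, strategy = st, interval = k, window_old = w,
          metric = c("brier", "auc", "hl", "calibration_intercept",
                     "calibration_slope", "n_updates"),
          value = c(pan$brier, pan$auc, pan$hl_statistic,
                    pan$calibration_intercept, pan$calibration_slope,
                    n_updates(run)),
          stringsAsFactors = FALSE)
      }
      sts <- names(runs)
      if (length(sts) > 1L) {
        qb <- vapply(sts, function(st) delta_bs_series(runs[[st]], never_run),
                     numeric(nq))
        for (i in seq_along(sts)[-length(sts)]) for (j in (i + 1):length(sts)) {
          d <- qb[, i] - qb[, j]  # per-quarter BS_a - BS_b
          pairwise[[length(pairwise) + 1L]] <- data.frame(
            replicate = r, interval = k, window_old = w,
            strategy_a = sts[i], strategy_b = sts[j],
            median_delta = stats::median(d),
            p_value = as.numeric(wilcoxon_signed_rank(d)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  structure(list(
    cells = cells,
    metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
    pairwise = if (length(pairwise))
      do.call(rbind, c(pairwise, list(make.row.names = FALSE))) else NULL,
    skipped = unlist(skipped),
    config = list(strategies = strategies, intervals = intervals,
                  windows_old = windows_old, alpha = alpha,
                  n_baseline = n_baseline, replicates = replicates,
                  seed = seed, g = g,
                  scenario_seed = if (is.null(cohorts)) scenario$seed else NA)
  ), class = "update_experiment")
}

#' @export
print.update_experiment <- function(x, ...) {
  cat("Update-strategy experiment:", length(x$cells), "grid cell(s),",
      x$config$replicates, "replicate(s)\n")
  cat("  strategies:", paste(x$config$strategies, collapse = ", "), "\n")
  cat("  intervals:", paste(x$config$intervals, collapse = ", "),
      " windows_old:", paste(x$config$windows_old, collapse = ", "), "\n")
  if (length(x$skipped)) cat("  skipped cells:", length(x$skipped), "\n")
  invisible(x)
}

#' Long-format per-quarter Brier-improvement table
#'
#' One row per (replicate, strategy, cell, quarter) with the Brier-score
#' difference versus never updating; negative values are improvements. The
#' summary component carries the per-cell median and interquartile range,
#' the quantities a boxplot of the improvement series displays.
#'
#' @param experiment an `update_experiment`.
#' @return list with `data` (long data frame) and `summary` (per-cell median
#'   and IQR).
#' @export
summarize_boxplot_data <- function(experiment) {
  rows <- lapply(experiment$cells, function(cl) {
    data.frame(replicate = cl$replicate, strategy = cl$strategy,
               interval = cl$interval, window_old = cl$window_old,
               quarter = as.integer(names(cl$delta_bs)),
               delta_bs = as.numeric(cl$delta_bs),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  key <- interaction(long$replicate, long$strategy, long$interval,
                     long$window_old, drop = TRUE)
  summ <- do.call(rbind, lapply(split(long, key), function(s) {
    qs <- stats::quantile(s$delta_bs, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(replicate = s$replicate[1L], strategy = s$strategy[1L],
               interval = s$interval[1L], window_old = s$window_old[1L],
               median = qs[2L], iqr = qs[3L] - qs[1L],
               q1 = qs[1L], q3 = qs[3L], stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(data = long, summary = summ)
}

#' @param x an `update_experiment`.
#' @param ... passed to [graphics::boxplot()].
#' @rdname summarize_boxplot_data
#' @export
plot.update_experiment <- function(x, ...) {
  bx <- summarize_boxplot_data(x)$data
  lab <- interaction(bx$strategy, paste0("k", bx$interval),
                     paste0("w", bx$window_old), drop = TRUE)
  graphics::boxplot(bx$delta_bs ~ lab, las = 2,
                    ylab = "Brier score difference vs never update", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write an experiment report bundle to CSV
#'
#' Emits `metrics.csv` (strategy x metric grid, long format),
#' `selections.csv` (closed-testing candidate tallies), `pairwise.csv`
#' (Wilcoxon comparisons), `boxplot.csv` (per-quarter improvement series),
#' `updates.csv` (all update events), and `manifest.json` (configuration
#' echo and package version).
#'
#' @param experiment an `update_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(experiment$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  sel <- lapply(experiment$cells, function(cl) {
    if (is.null(cl$tally)) return(NULL)
    data.frame(replicate = cl$replicate, interval = cl$interval,
               window_old = cl$window_old,
               candidate = names(cl$tally), count = as.integer(cl$tally),
               stringsAsFactors = FALSE)
  })
  sel <- do.call(rbind, c(sel, list(make.row.names = FALSE)))
  if (!is.null(sel))
    utils::write.csv(sel, file.path(dir, "selections.csv"), row.names = FALSE)
  if (!is.null(experiment$pairwise))
    utils::write.csv(experiment$pairwise, file.path(dir, "pairwise.csv"),
                     row.names = FALSE)
  bx <- summarize_boxplot_data(experiment)
  utils::write.csv(bx$data, file.path(dir, "boxplot.csv"), row.names = FALSE)
  upd <- lapply(experiment$cells, function(cl) {
    if (!nrow(cl$run$updates)) return(NULL)
    cbind(data.frame(replicate = cl$replicate, strategy = cl$strategy,
                     interval = cl$interval, window_old = cl$window_old),
          cl$run$updates)
  })
  upd <- do.call(rbind, c(upd, list(make.row.names = FALSE)))
  if (!is.null(upd))
    utils::write.csv(upd, file.path(dir, "updates.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(experiment$config,
      list(package_version = as.character(utils::packageVersion("dyncal")))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
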