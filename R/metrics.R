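#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better, 0 is a perfect forecast.
#'
#' @param p probability vector in \[0, 1\].
#' @param y binary outcome vector of the same length.
#' @return the score, in \[0, 1\].
#' @export
brier <- function(p, y) {
  if (length(p) == 0L) stop("empty input", call. = FALSE)
  if (length(p) != length(y)) stop("p and y lengths differ", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities outside [0, 1]", call. = FALSE)
  check_binary_outcome(y)
  mean((p - y)^2)
}

#' C-statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen event receives a higher predicted
#' risk than a randomly chosen non-event, ties counted 1/2; computed from the
#' rank-sum form, which equals the trapezoidal ROC area.
#'
#' @inheritParams brier
#' @return concordance probability in \[0, 1\].
#' @export
auc <- function(p, y) {
  check_binary_outcome(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one event and one non-event",
         call. = FALSE)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow goodness-of-fit statistic
#'
#' Patients are ranked by predicted probability into `g` quantile groups
#' (ties at a cut go to the lower group). Within each group the statistic
#' accumulates `(O1-E1)^2/E1 + (O0-E0)^2/E0` where `E1` is the sum of
#' predicted probabilities. Groups whose expected event or non-event count is
#' zero are collapsed into their neighbor; the effective group count is
#' reported.
#'
#' @inheritParams brier
#' @param g number of quantile groups (default 10, i.e. deciles).
#' @return list with `statistic` (>= 0) and `g_effective`.
#' @export
hosmer_lemeshow <- function(p, y, g = 10L) {
  check_binary_outcome(y)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(p) < g) stop("fewer observations than groups", call. = FALSE)
  brk <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1L)))
  grp <- if (length(brk) < 3L) rep(1L, length(p))
         else as.integer(cut(p, breaks = brk, include.lowest = TRUE))
  agg <- function(grp) {
    ids <- sort(unique(grp))
    t(vapply(ids, function(gid) {
      sel <- grp == gid
      c(O1 = sum(y[sel]), E1 = sum(p[sel]),
        O0 = sum(sel) - sum(y[sel]), E0 = sum(sel) - sum(p[sel]))
    }, numeric(4)))
  }
  tab <- agg(grp)
  # collapse degenerate groups (zero expected events or non-events) into a neighbor
  while (nrow(tab) > 1L && any(tab[, "E1"] <= 0 | tab[, "E0"] <= 0)) {
    i <- which(tab[, "E1"] <= 0 | tab[, "E0"] <= 0)[1L]
    j <- if (i == 1L) 2L else i - 1L
    tab[j, ] <- tab[j, ] + tab[i, ]
    tab <- tab[-i, , drop = FALSE]
  }
  stat <- sum((tab[, "O1"] - tab[, "E1"])^2 / tab[, "E1"] +
              (tab[, "O0"] - tab[, "E0"])^2 / tab[, "E0"])
  list(statistic = stat, g_effective = nrow(tab))
}

#' Logistic calibration intercept and slope
#'
#' The calibration slope is the MLE of `beta` in
#' `logit(P(y=1)) = alpha + beta * logit(p)` (the free two-parameter logistic
#' calibration); the calibration intercept is reported as
#' calibration-in-the-large, the MLE of `alpha` with the slope fixed at 1
#' (`logit(p)` as offset). Both fits are returned so either convention can be
#' tabulated. Probabilities are clipped to `[1e-12, 1 - 1e-12]` before the
#' logit; the number of clipped values is reported.
#'
#' @inheritParams brier
#' @return list with `intercept` (calibration-in-the-large), `slope`,
#'   `joint` (the `c(alpha, beta)` of the two-parameter fit), `n_clipped`.
#'   When `logit(p)` is constant the slope is undefined and returned as `NA`
#'   (with a warning); the intercept is still returned.
#' @export
calibration_intercept_slope <- function(p, y) {
  check_binary_outcome(y)
  if (all(y == 1) || all(y == 0))
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  pc <- clip_prob(p)
  n_clipped <- attr(pc, "n_clipped")
  lp <- logit(as.numeric(pc))
  citl <- irls_logistic(matrix(1, length(y), 1L), y, offset = lp)$coefficients[1L]
  if (length(unique(lp)) == 1L) {
    warning("calibration slope undefined: logit(p) is constant")
    return(list(intercept = unname(citl), slope = NA_real_,
                joint = c(NA_real_, NA_real_), n_clipped = n_clipped))
  }
  jt <- irls_logistic(cbind(1, lp), y)$coefficients
  list(intercept = unname(citl), slope = unname(jt[2L]),
       joint = unname(jt), n_clipped = n_clipped)
}

#' Full performance panel for one set of predictions
#'
#' @inheritParams hosmer_lemeshow
#' @return object of class `metric_panel`: `brier`, `auc`, `hl_statistic`,
#'   `hl_groups`, `calibration_intercept`, `calibration_slope`, `n`,
#'   `n_events`.
#' @export
metric_panel <- function(p, y, g = 10L) {
  hl <- hosmer_lemeshow(p, y, g = g)
  cal <- calibration_intercept_slope(p, y)
  structure(list(
    brier = brier(p, y),
    auc = auc(p, y),
    hl_statistic = hl$statistic,
    hl_groups = hl$g_effective,
    calibration_intercept = cal$intercept,
    calibration_slope = cal$slope,
    n = length(y),
    n_events = sum(y)
  ), class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf("  n = %d (%d events)\n", x$n, x$n_events))
  cat(sprintf("  Brier score            %.4f\n", x$brier))
  cat(sprintf("  AUC                    %.4f\n", x$auc))
  cat(sprintf("  Hosmer-Lemeshow        %.2f (g = %d)\n",
              x$hl_statistic, x$hl_groups))
  cat(sprintf("  Calibration intercept  %.4f\n", x$calibration_intercept))
  cat(sprintf("  Calibration slope      %.4f\n", x$calibration_slope))
  invisible(x)
}

#' Per-quarter Brier-score difference between two runs
#'
#' Element `q` is `BS_a(q) - BS_b(q)`; negative values mean `run_a` improves
#' on `run_b` (conventionally the never-update run) at quarter `q`.
#'
#' @param run_a,run_b two `update_run` objects over identical cohorts.
#' @return named numeric vector, one element per post-baseline quarter.
#' @export
delta_bs_series <- function(run_a, run_b) {
  pa <- run_a$predictions; pb <- run_b$predictions
  if (nrow(pa) != nrow(pb) ||
      !identical(pa$quarter, pb$quarter) || !identical(pa$y, pb$y))
    stop("runs do not cover identical cohorts", call. = FALSE)
  lev <- sort(unique(pa$quarter))
  qa <- split(pa, factor(pa$quarter, levels = lev))
  qb <- split(pb, factor(pb$quarter, levels = lev))
  out <- vapply(names(qa), function(q) {
    brier(qa[[q]]$p, qa[[q]]$y) - brier(qb[[q]]$p, qb[[q]]$y)
  }, numeric(1))
  out
}

#' Two-sided Wilcoxon signed-rank test for paired differences
#'
#' Zeros are removed; for up to 25 nonzero differences without ties in the
#' absolute values the exact null distribution of the signed-rank statistic is
#' used, otherwise the normal approximation with continuity and tie
#' correction. When every difference is zero the test carries no information
#' and `p = 1` is returned by convention.
#'
#' @param deltas vector of paired differences.
#' @return two-sided p-value in \[0, 1\], with attributes `statistic` (W,
#'   sum of positive ranks) and `exact` (logical path marker).
#' @export
wilcoxon_signed_rank <- function(deltas) {
  if (length(deltas) == 0L) stop("empty input", call. = FALSE)
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0L) {
    out <- 1
    attr(out, "statistic") <- NA_real_
    attr(out, "exact") <- FALSE
    return(out)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    p <- 2 * min(stats::psignrank(W, n),
                 stats::psignrank(W - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  attr(p, "statistic") <- W
  attr(p, "exact") <- exact
  p
}

#' Weighted average number of parameters re-estimated per update
#'
#' For a data-driven selection procedure the per-update parameter cost is the
#' selection-count-weighted average of the candidate costs:
#' `sum(costs * counts) / n_updates`.
#'
#' @param counts how often each candidate was selected.
#' @param costs parameters re-estimated by each candidate (same order).
#' @param n_updates denominator: total updates performed (or update
#'   opportunities, depending on the tabulation convention).
#' @return the weighted average (real).
#' @export
weighted_param_average <- function(counts, costs, n_updates) {
  if (length(counts) != length(costs))
    stop("counts and costs lengths differ", call. = FALSE)
  if (n_updates <= 0) stop("n_updates must be positive", call. = FALSE)
  sum(costs * counts) / n_updates
}
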