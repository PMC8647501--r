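# Independent oracles used across the suite. None of these call the package's
# fitting code paths: they are brute-force or root-finding re-derivations.

# 1-D score-equation root for an intercept-only logistic recalibration:
# solves sum(y - plogis(a + lp)) = 0 by bisection.
bisection_intercept <- function(lp, y, lower = -30, upper = 30, tol = 1e-12) {
  f <- function(a) sum(y - plogis(a + lp))
  stopifnot(f(lower) * f(upper) <= 0)
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (f(lower) * f(mid) <= 0) upper <- mid else lower <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}

# 2-D Newton-Raphson for logit(P(y=1)) = a + b*lp, run from multiple starts;
# returns the (a, b) with the best log-likelihood among converged runs.
newton_ab <- function(lp, y, starts = NULL, tol = 1e-12) {
  ll <- function(ab) {
    eta <- ab[1] + ab[2] * lp
    sum(y * eta - log1p(exp(eta)))
  }
  run <- function(ab) {
    for (i in 1:200) {
      eta <- ab[1] + ab[2] * lp
      mu <- plogis(eta)
      w <- mu * (1 - mu)
      score <- c(sum(y - mu), sum((y - mu) * lp))
      info <- rbind(c(sum(w), sum(w * lp)),
                    c(sum(w * lp), sum(w * lp^2)))
      step <- tryCatch(solve(info, score), error = function(e) return(NULL))
      if (is.null(step)) return(NULL)
      ab <- ab + step
      if (max(abs(score)) < tol) break
    }
    if (max(abs(c(sum(y - plogis(ab[1] + ab[2] * lp)),
                  sum((y - plogis(ab[1] + ab[2] * lp)) * lp)))) > 1e-6)
      return(NULL)
    ab
  }
  if (is.null(starts))
    starts <- cbind(runif(10, -2, 2), runif(10, -1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    ab <- run(starts[i, ])
    if (!is.null(ab) && (is.null(best) || ll(ab) > ll(best))) best <- ab
  }
  best
}

# AUC by exhaustive enumeration of (event, non-event) pairs, ties as 1/2.
auc_bruteforce <- function(p, y) {
  pe <- p[y == 1]; pn <- p[y == 0]
  tot <- 0
  for (a in pe) for (b in pn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pe) * length(pn))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign assignments
# of the observed absolute differences.
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Hosmer-Lemeshow sum computed directly from given group assignments.
hl_manual <- function(p, y, grp) {
  s <- 0
  for (gid in unique(grp)) {
    sel <- grp == gid
    O1 <- sum(y[sel]); E1 <- sum(p[sel])
    O0 <- sum(sel) - O1; E0 <- sum(sel) - E1
    s <- s + (O1 - E1)^2 / E1 + (O0 - E0)^2 / E0
  }
  s
}

# Compact drift scenario (6 parameters) for fast engine tests: the likelihood
# asymptotics hold comfortably at a few hundred observations per fit.
tiny_scenario <- function(n_quarters = 4, n_per_quarter = 300, seed = 1,
                          intercept_drift = function(q) 0,
                          slope_drift = function(q) 1,
                          fixed_size = TRUE,
                          baseline_intercept = -1.6) {
  drift_scenario(
    n_quarters = n_quarters, n_per_quarter = n_per_quarter,
    baseline_intercept = baseline_intercept,
    baseline_slopes = c(x1 = 0.5, x2 = -0.4, z = 0.7,
                        g_b = 0.3, g_c = -0.3),
    covariates = list(
      covariate_continuous("x1", 0, 1),
      covariate_continuous("x2", 0, 1),
      covariate_binary("z", 0.3),
      covariate_categorical("g", c("a", "b", "c"), c(0.5, 0.3, 0.2))
    ),
    intercept_drift = intercept_drift, slope_drift = slope_drift,
    fixed_size = fixed_size, seed = seed
  )
}

# random logistic data for property tests (p predictors, no structure)
random_dataset <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  beta <- rnorm(p, 0, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + X %*% beta))
  if (all(y == y[1])) y[1] <- 1 - y[1]
  list(X = X, y = y)
}
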