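test_that("Brier score arithmetic", {
  y <- c(0, 1, 1, 0)
  expect_equal(brier(y, y), 0)
  expect_equal(brier(rep(0.5, 4), y), 0.25)
  expect_equal(brier(c(0.2, 0.7), c(0, 1)), 0.065)
  expect_error(brier(numeric(0), numeric(0)), "empty")
  expect_error(brier(c(0.5, 1.2), c(0, 1)), "outside")
})

test_that("AUC equals exhaustive pair enumeration and is rank-invariant", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  p8 <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.6, 0.2, 0.7)
  y8 <- c(0, 0, 1, 1, 1, 0, 0, 1)
  expect_equal(auc(p8, y8), auc_bruteforce(p8, y8))
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    p <- round(runif(n), 2)  # induce occasional ties
    y <- rbinom(n, 1, 0.5)
    if (all(y == y[1])) y[1] <- 1 - y[1]
    expect_equal(auc(p, y), auc_bruteforce(p, y))
    expect_equal(auc(plogis(5 * p - 2), y), auc(p, y))  # increasing transform
  }
  expect_error(auc(c(0.2, 0.3), c(1, 1)), "undefined")
})

test_that("Hosmer-Lemeshow matches manual group sums and is zero under exact calibration", {
  # exactly calibrated two-group instance
  p <- rep(c(0.2, 0.8), each = 10)
  y <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  hl <- hosmer_lemeshow(p, y, g = 2)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$g_effective, 2)
  # hand-computed 2-group toy at n = 20
  set.seed(9)
  p2 <- sort(runif(20, 0.05, 0.95))
  y2 <- rbinom(20, 1, p2)
  if (all(y2 == y2[1])) y2[1] <- 1 - y2[1]
  grp <- rep(1:2, each = 10)
  expect_equal(hosmer_lemeshow(p2, y2, g = 2)$statistic,
               hl_manual(p2, y2, grp))
  # statistic depends on the groups only through their sums
  p3 <- ave(p2, grp)  # replace by group means: same membership, same sums
  expect_equal(hosmer_lemeshow(p3, y2, g = 2)$statistic,
               hosmer_lemeshow(p2, y2, g = 2)$statistic, tolerance = 1e-12)
  expect_gte(hosmer_lemeshow(p2, y2, g = 5)$statistic, 0)
  expect_error(hosmer_lemeshow(p2, y2, g = 1), "at least 2")
  expect_error(hosmer_lemeshow(p2[1:3], y2[1:3], g = 5), "fewer")
})

test_that("logistic calibration returns (0, 1) in-sample and matches root-finding oracles", {
  set.seed(15)
  d <- random_dataset(200, 3, seed = 15)
  fit <- fit_logistic(d$X, d$y)
  p_hat <- predict(fit$model, d$X)
  cal <- calibration_intercept_slope(p_hat, d$y)
  expect_lt(abs(cal$intercept), 1e-6)
  expect_lt(abs(cal$slope - 1), 1e-6)
  # oracle agreement on an out-of-sample instance
  y2 <- rbinom(200, 1, plogis(-0.7 + 1.8 * qlogis(p_hat)))
  if (all(y2 == y2[1])) y2[1] <- 1 - y2[1]
  cal2 <- calibration_intercept_slope(p_hat, y2)
  expect_equal(cal2$intercept, bisection_intercept(qlogis(p_hat), y2),
               tolerance = 1e-8)
  expect_equal(unname(cal2$joint), newton_ab(qlogis(p_hat), y2),
               tolerance = 1e-8)
  # constant predictions: slope undefined, intercept still returned
  expect_warning(c3 <- calibration_intercept_slope(rep(0.3, 50),
                                                   rbinom(50, 1, 0.5)),
                 "constant")
  expect_true(is.na(c3$slope))
  expect_true(is.finite(c3$intercept))
})

test_that("systematic overprediction by +1 logit is recovered as intercept -1, slope 1", {
  set.seed(19)
  n <- 50000
  lp_true <- rnorm(n, -1.5, 0.8)
  y <- rbinom(n, 1, plogis(lp_true))
  p_over <- plogis(lp_true + 1)
  cal <- calibration_intercept_slope(p_over, y)
  expect_lt(abs(cal$intercept - (-1)), 0.05)
  expect_lt(abs(cal$slope - 1), 0.05)
})

test_that("per-quarter Brier differences recompute from raw records and sum to the pooled gap", {
  sc <- tiny_scenario(n_quarters = 6, n_per_quarter = 200, seed = 33,
                      intercept_drift = function(q) -0.1 * q)
  sp <- split_baseline(generate_cohorts(sc), 2)
  never <- run_dynamic_update(sp$baseline, sp$post, update_schedule("never"))
  rec <- run_dynamic_update(sp$baseline, sp$post,
                            update_schedule("recal_intercept", interval = 1))
  expect_equal(unname(delta_bs_series(never, never)), rep(0, 4))
  d <- delta_bs_series(rec, never)
  expect_length(d, 4)
  # quarter-wise recomputation from raw prediction records
  for (q in 0:3) {
    ra <- rec$predictions[rec$predictions$quarter == q, ]
    rn <- never$predictions[never$predictions$quarter == q, ]
    expect_equal(unname(d[as.character(q)]),
                 brier(ra$p, ra$y) - brier(rn$p, rn$y))
  }
  # cohort-size-weighted sum of per-quarter deltas equals the pooled difference
  sizes <- table(rec$predictions$quarter)
  pooled_gap <- brier(rec$predictions$p, rec$predictions$y) -
    brier(never$predictions$p, never$predictions$y)
  expect_equal(sum(d * as.integer(sizes)) / sum(sizes), pooled_gap)
  # cohort mismatch errors
  short <- rec
  short$predictions <- short$predictions[-1, ]
  expect_error(delta_bs_series(short, never), "identical cohorts")
})

test_that("Wilcoxon signed-rank p-values match exhaustive sign enumeration", {
  set.seed(25)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    expect_equal(as.numeric(wilcoxon_signed_rank(d)), wilcoxon_enum(d),
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(wilcoxon_signed_rank(rep(0, 5))), 1)
  expect_error(wilcoxon_signed_rank(numeric(0)), "empty")
})

test_that("exact and normal-approximation Wilcoxon paths agree at n = 24", {
  normal_path <- function(d) {
    d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d)); W <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * pnorm(-abs(z)))
  }
  set.seed(35)
  for (rep in 1:25) {
    d <- rnorm(24, mean = runif(1, -0.3, 0.3))
    p_exact <- wilcoxon_signed_rank(d)
    expect_true(attr(p_exact, "exact"))
    expect_lt(abs(as.numeric(p_exact) - normal_path(d)), 0.02)
  }
})

test_that("weighted parameter accounting follows the selection-count convention", {
  expect_equal(weighted_param_average(c(3, 4, 5), c(1, 2, 15), 12), 86 / 12)
  expect_equal(round(weighted_param_average(c(3, 4, 5), c(1, 2, 15), 12), 1), 7.2)
  expect_equal(weighted_param_average(6, 15, 6), 15)
  expect_equal(weighted_param_average(c(0, 0, 0), c(1, 2, 15), 12), 0)
  expect_error(weighted_param_average(c(1, 2), c(1, 2, 15), 3), "lengths")
  expect_error(weighted_param_average(c(1, 2, 3), c(1, 2, 15), 0), "positive")
})
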