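test_that("recalibration chains collapse algebraically to a single affine map", {
  set.seed(1)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    chain <- lapply(seq_len(k), function(i) runif(2, -2, 2))
    beta <- c(runif(1, -2, 2), runif(3, -1, 1))
    m <- pred_model(beta, chain = chain)
    X <- matrix(rnorm(5 * 3), 5, 3)
    lp0 <- beta[1] + drop(X %*% beta[-1])
    lp_seq <- lp0
    for (mp in chain) lp_seq <- mp[1] + mp[2] * lp_seq
    expect_equal(linear_predictor(m, X), lp_seq, tolerance = 1e-12)
  }
  # two unit shifts equal one double shift
  m1 <- pred_model(c(0.3, 1), chain = list(c(1, 1), c(1, 1)))
  m2 <- pred_model(c(0.3, 1), chain = list(c(2, 1)))
  X <- matrix(rnorm(50), 50, 1)
  expect_equal(linear_predictor(m1, X), linear_predictor(m2, X), tolerance = 1e-12)
  # explicit composition formula on 100 random inputs
  a1 <- 0.7; b1 <- -1.3; a2 <- 0.2; b2 <- 2.1
  mc <- pred_model(c(0.1, 0.5), chain = list(c(a1, b1), c(a2, b2)))
  ms <- pred_model(c(0.1, 0.5), chain = list(c(a2 + b2 * a1, b2 * b1)))
  X <- matrix(rnorm(100), 100, 1)
  expect_equal(linear_predictor(mc, X), linear_predictor(ms, X), tolerance = 1e-12)
})

test_that("all-zero coefficients with empty chain predict probability one half", {
  m <- pred_model(c(0, 0, 0))
  X <- matrix(rnorm(10 * 2), 10, 2)
  expect_equal(linear_predictor(m, X), rep(0, 10))
  expect_equal(predict(m, X), rep(0.5, 10))
  expect_error(linear_predictor(m, matrix(0, 3, 5)), "columns")
})

test_that("fit_logistic matches the closed-form saturated binary-cell solution", {
  x <- rep(c(0, 1), each = 40)
  y <- c(rep(1, 10), rep(0, 30), rep(1, 20), rep(0, 20))
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  expect_equal(unname(coef(fit$model)[1]), qlogis(0.25), tolerance = 1e-8)
  expect_equal(unname(coef(fit$model)[2]), qlogis(0.5) - qlogis(0.25),
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_parameters_reestimated, 2L)
})

test_that("degenerate outcomes error and zero-variance columns are dropped with coefficient zero", {
  X <- matrix(rnorm(30), 30, 1)
  expect_error(fit_logistic(X, rep(1, 30)), "degenerate")
  X2 <- cbind(a = rnorm(60), const = 1.7)
  y <- rbinom(60, 1, 0.4); y[1] <- 1; y[2] <- 0
  fit <- fit_logistic(X2, y)
  expect_equal(unname(coef(fit$model)["const"]), 0)
  expect_true("const" %in% fit$dropped_columns)
  expect_equal(fit$n_parameters_reestimated, 2L)
})

test_that("detected separation reports converged = FALSE without an exception", {
  x <- c(rnorm(20, -2), rnorm(20, 2))
  y <- as.numeric(x > 0)
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  expect_false(fit$converged)
})

test_that("intercept recalibration solves the one-dimensional score equation", {
  # constant lp: closed form
  m <- pred_model(c(0, 0))
  X <- matrix(rnorm(40), 40, 1)
  y <- rep(c(1, 0), c(10, 30))
  res <- recalibrate_intercept(m, X, y)
  expect_equal(res$model$chain[[1]][1], qlogis(0.25), tolerance = 1e-8)
  expect_equal(res$model$chain[[1]][2], 1)
  expect_equal(res$n_parameters_reestimated, 1L)
  # in-sample idempotence: a second recalibration shifts by ~0
  res2 <- recalibrate_intercept(res$model, X, y)
  expect_lt(abs(res2$model$chain[[2]][1]), 1e-8)
  # bisection oracle on a random instance
  set.seed(21)
  d <- random_dataset(150, 3, seed = 21)
  m0 <- fit_logistic(d$X, d$y)$model
  y_new <- rbinom(150, 1, plogis(linear_predictor(m0, d$X) + 0.8))
  if (all(y_new == y_new[1])) y_new[1] <- 1 - y_new[1]
  r <- recalibrate_intercept(m0, d$X, y_new)
  a_oracle <- bisection_intercept(linear_predictor(m0, d$X), y_new)
  expect_equal(r$model$chain[[1]][1], a_oracle, tolerance = 1e-8)
})

test_that("intercept-and-slope recalibration is the two-parameter logistic calibration MLE", {
  set.seed(31)
  d <- random_dataset(200, 4, seed = 31)
  m <- fit_logistic(d$X, d$y)$model
  # freshly refit then recalibrated in-sample gives (0, 1)
  r <- recalibrate_slope(m, d$X, d$y)
  expect_equal(r$model$chain[[1]], c(0, 1), tolerance = 1e-6)
  expect_equal(r$n_parameters_reestimated, 2L)
  # constant lp is unidentifiable
  mc <- pred_model(c(0.4, 0))
  expect_error(recalibrate_slope(mc, d$X[, 1, drop = FALSE], d$y),
               "unidentifiable")
  # multi-start Newton oracle at n = 30
  set.seed(32)
  X <- matrix(rnorm(30 * 2), 30, 2)
  m2 <- pred_model(c(-0.3, 0.8, -0.5))
  lp <- linear_predictor(m2, X)
  y <- rbinom(30, 1, plogis(0.4 + 1.6 * lp))
  if (all(y == y[1])) y[1] <- 1 - y[1]
  r2 <- recalibrate_slope(m2, X, y)
  ab <- newton_ab(lp, y)
  expect_equal(r2$model$chain[[1]], ab, tolerance = 1e-8)
})

test_that("refit equals fit_logistic, empties the chain and counts all parameters", {
  set.seed(41)
  d <- random_dataset(120, 4, seed = 41)
  m <- pred_model(rnorm(5), chain = list(c(0.2, 1.4)))
  r <- refit(m, d$X, d$y)
  f <- fit_logistic(d$X, d$y)
  expect_equal(coef(r$model), coef(f$model))
  expect_length(r$model$chain, 0)
  expect_equal(r$n_parameters_reestimated, 5L)
  # default registry-like design: 14 columns -> 15 parameters
  sc <- default_scenario(n_quarters = 1, n_per_quarter = 3000, seed = 10,
                         fixed_size = TRUE)
  ch <- generate_cohorts(sc)[[1]]
  stopifnot(all(apply(ch$X, 2, var) > 0))
  rf <- refit(pred_model(rep(0, 15)), ch$X, ch$y)
  expect_equal(rf$n_parameters_reestimated, 15L)
})

test_that("log-likelihoods are monotone along the nested update chain", {
  for (seed in c(7, 17, 27)) {
    d <- random_dataset(180, 4, seed = seed)
    m <- pred_model(c(-1, rnorm(4, 0, 0.4)))
    ll0 <- dyncal:::model_loglik(m, d$X, d$y)
    lp <- linear_predictor(m, d$X)
    ll1 <- recalibrate_intercept(m, d$X, d$y)$log_likelihood
    ll2 <- recalibrate_slope(m, d$X, d$y)$log_likelihood
    ll3 <- refit(m, d$X, d$y)$log_likelihood
    expect_true(ll0 <= ll1 + 1e-8 && ll1 <= ll2 + 1e-8 && ll2 <= ll3 + 1e-8)
  }
})

test_that("model serialization round-trips doubles bit-faithfully", {
  m <- pred_model(c(`(Intercept)` = -1.234567890123456789, a = pi, b = -exp(1)),
                  chain = list(c(1 / 3, sqrt(2)), c(-0.1, 1)),
                  provenance = list(strategy = "recal_intercept", quarter = 7))
  f <- tempfile(fileext = ".json")
  write_pred_model(m, f)
  back <- read_pred_model(f)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$chain, m$chain)
  expect_equal(back$provenance$strategy, "recal_intercept")
})
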