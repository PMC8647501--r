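#' Logistic prediction model with a recalibration chain
#'
#' A prediction model is a set of origin coefficients on the log-odds scale
#' (intercept first) plus an ordered chain of affine recalibration maps
#' `(a, b)` applied to the origin linear predictor. Intercept recalibration
#' appends `(a, 1)`; intercept-and-slope recalibration appends `(a, b)`; a
#' refit replaces the origin coefficients and empties the chain. The chain
#' always collapses algebraically to a single affine map (see
#' [collapse_chain()]).
#'
#' @param coefficients named numeric vector, `(Intercept)` first, then one
#'   slope per predictor column.
#' @param chain list of length-2 numeric vectors `c(a, b)`; default empty.
#' @param provenance free-form list tag (strategy label, quarter of last
#'   update).
#' @return an object of class `pred_model`.
#' @export
pred_model <- function(coefficients, chain = list(), provenance = list()) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L)
  if (is.null(names(coefficients)))
    names(coefficients) <- c("(Intercept)",
                             paste0("x", seq_len(length(coefficients) - 1L)))
  chain <- lapply(chain, function(m) {
    m <- as.numeric(m)
    stopifnot(length(m) == 2L)
    m
  })
  structure(list(coefficients = coefficients, chain = chain,
                 provenance = provenance),
            class = "pred_model")
}

#' @export
coef.pred_model <- function(object, ...) object$coefficients

#' @export
print.pred_model <- function(x, ...) {
  cat("Logistic prediction model:", length(x$coefficients), "origin parameters,",
      length(x$chain), "recalibration map(s) in chain\n")
  ab <- collapse_chain(x)
  cat(sprintf("  collapsed chain: a = %.6g, b = %.6g\n", ab[1], ab[2]))
  if (!is.null(x$provenance$strategy))
    cat("  provenance:", x$provenance$strategy,
        if (!is.null(x$provenance$quarter))
          paste0("(last update at quarter ", x$provenance$quarter, ")"), "\n")
  invisible(x)
}

#' Collapse a recalibration chain to a single affine map
#'
#' Maps `(a1,b1),...,(ak,bk)` applied in order to a linear predictor `lp`
#' compose to the single map `(a, b)` with `lp_final = a + b * lp`; the
#' composition of `(a1,b1)` then `(a2,b2)` is `(a2 + b2*a1, b2*b1)`.
#'
#' @param model a `pred_model`.
#' @return numeric `c(a, b)` of the collapsed map (`c(0, 1)` for an empty
#'   chain).
#' @export
collapse_chain <- function(model) {
  a <- 0; b <- 1
  for (m in model$chain) {
    a <- m[1] + m[2] * a
    b <- m[2] * b
  }
  c(a = a, b = b)
}

#' Linear predictor of a prediction model
#'
#' Returns `a + b * (beta0 + X %*% beta)` per row, where `(a, b)` is the
#' collapsed recalibration chain.
#'
#' @param model a `pred_model`.
#' @param X predictor matrix with `length(coef(model)) - 1` columns.
#' @return numeric vector of log-odds.
#' @export
linear_predictor <- function(model, X) {
  X <- as.matrix(X)
  beta <- model$coefficients
  if (ncol(X) != length(beta) - 1L)
    stop(sprintf("X has %d columns but the model expects %d",
                 ncol(X), length(beta) - 1L), call. = FALSE)
  ab <- collapse_chain(model)
  lp0 <- beta[1L] + drop(X %*% beta[-1L])
  unname(ab[1L] + ab[2L] * lp0)
}

#' @param object a `pred_model`.
#' @param newdata predictor matrix.
#' @param type `"response"` for probabilities (default) or `"link"` for
#'   log-odds.
#' @param ... unused.
#' @rdname linear_predictor
#' @export
predict.pred_model <- function(object, newdata, type = c("response", "link"),
                               ...) {
  type <- match.arg(type)
  lp <- linear_predictor(object, newdata)
  if (type == "link") lp else expit(lp)
}

# Bernoulli log-likelihood of a model's predictions on (X, y)
model_loglik <- function(model, X, y) {
  p <- clip_prob(predict(model, X))
  sum(y * log(p) + (1 - y) * log1p(-p))
}

# internal: IRLS logistic fit via glm.fit with honest convergence reporting.
# Returns list(coefficients, loglik, converged, separated).
irls_logistic <- function(Xd, y, offset = NULL) {
  warned01 <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   offset = offset,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned01 <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  co <- fit$coefficients
  co[is.na(co)] <- 0
  mu <- clip_prob(fit$fitted.values)
  list(coefficients = co,
       loglik = sum(y * log(mu) + (1 - y) * log1p(-mu)),
       converged = isTRUE(fit$converged) && !warned01,
       separated = warned01,
       aliased = is.na(fit$coefficients))
}

# result wrapper shared by all update operations
fit_result <- function(model, n_reest, loglik, converged, dropped = character()) {
  structure(list(model = model,
                 n_parameters_reestimated = as.integer(n_reest),
                 log_likelihood = loglik,
                 converged = converged,
                 dropped_columns = dropped),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: %d parameter(s) re-estimated, logLik %.4f, converged: %s\n",
              x$n_parameters_reestimated, x$log_likelihood, x$converged))
  if (length(x$dropped_columns))
    cat("  dropped (zero-variance/aliased):",
        paste(x$dropped_columns, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.fit_result <- function(object, ...) object$log_likelihood

#' Maximum-likelihood logistic regression fit
#'
#' Fits `logit(P(y=1)) = b0 + X %*% b` by IRLS. Zero-variance (and otherwise
#' aliased) columns are dropped from estimation, given coefficient exactly 0,
#' and reported in `dropped_columns`, so sequential refits never fail on rare
#' predictors absent from a small cohort. Detected separation is reported as
#' `converged = FALSE` (the iteration-cap estimate is kept), never an error.
#'
#' @param X predictor matrix (no intercept column).
#' @param y binary outcome vector with at least one event and one non-event.
#' @param provenance provenance tag stored on the resulting model.
#' @return a `fit_result` whose `model` has an empty recalibration chain.
#' @export
fit_logistic <- function(X, y, provenance = list(strategy = "fit")) {
  X <- as.matrix(X)
  check_binary_outcome(y)
  if (nrow(X) != length(y))
    stop("X and y disagree on the number of patients", call. = FALSE)
  if (all(y == 1) || all(y == 0))
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  cn <- colnames(X)
  if (is.null(cn)) cn <- colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2L, function(col) length(unique(col)) > 1L)
  fit <- irls_logistic(cbind(`(Intercept)` = 1, X[, keep, drop = FALSE]), y)
  aliased <- fit$aliased[-1L]
  dropped <- c(cn[!keep], cn[keep][aliased])
  beta <- stats::setNames(numeric(ncol(X) + 1L), c("(Intercept)", cn))
  beta[c("(Intercept)", cn[keep])] <- fit$coefficients
  model <- pred_model(beta, chain = list(), provenance = provenance)
  fit_result(model,
             n_reest = 1L + sum(keep) - sum(aliased),
             loglik = fit$loglik, converged = fit$converged,
             dropped = dropped)
}

#' Update a deployed model by intercept recalibration
#'
#' Re-estimates only a log-odds shift: the MLE of `alpha` in
#' `logit(P(y=1)) = alpha + lp` with the current linear predictor `lp` held
#' fixed as an offset. The map `(alpha, 1)` is appended to the model's
#' recalibration chain. Only `(lp, y)` pairs are needed, so `lp` may be
#' supplied directly in place of `X` (useful when patient-level predictors
#' cannot be shared).
#'
#' @param model the currently deployed `pred_model`.
#' @param X predictor matrix (ignored when `lp` is given).
#' @param y binary outcome vector.
#' @param lp optional precomputed linear predictor of `model` on the update
#'   data.
#' @param provenance provenance tag for the updated model.
#' @return a `fit_result` with `n_parameters_reestimated = 1`.
#' @export
recalibrate_intercept <- function(model, X = NULL, y, lp = NULL,
                                  provenance = model$provenance) {
  if (is.null(lp)) lp <- linear_predictor(model, X)
  check_binary_outcome(y)
  if (all(y == 1) || all(y == 0))
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  fit <- irls_logistic(matrix(1, length(y), 1L), y, offset = lp)
  upd <- pred_model(model$coefficients,
                    chain = c(model$chain, list(c(unname(fit$coefficients[1L]), 1))),
                    provenance = provenance)
  fit_result(upd, 1L, fit$loglik, fit$converged)
}

#' Update a deployed model by intercept-and-slope recalibration
#'
#' Re-estimates the two-parameter logistic calibration
#' `logit(P(y=1)) = alpha + beta * lp` of the current linear predictor and
#' appends `(alpha, beta)` to the chain. Like intercept recalibration it needs
#' only `(lp, y)` pairs.
#'
#' @inheritParams recalibrate_intercept
#' @return a `fit_result` with `n_parameters_reestimated = 2`.
#' @export
recalibrate_slope <- function(model, X = NULL, y, lp = NULL,
                              provenance = model$provenance) {
  if (is.null(lp)) lp <- linear_predictor(model, X)
  check_binary_outcome(y)
  if (all(y == 1) || all(y == 0))
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  if (length(unique(lp)) == 1L)
    stop("unidentifiable slope: linear predictor is constant", call. = FALSE)
  fit <- irls_logistic(cbind(1, lp), y)
  upd <- pred_model(model$coefficients,
                    chain = c(model$chain, list(unname(fit$coefficients))),
                    provenance = provenance)
  fit_result(upd, 2L, fit$loglik, fit$converged)
}

#' Update by full refit (model revision)
#'
#' Re-estimates every coefficient on the update data, returning a brand-new
#' model with an empty recalibration chain; `n_parameters_reestimated` is the
#' number of effectively estimated parameters (intercept plus non-degenerate
#' columns).
#'
#' @inheritParams recalibrate_intercept
#' @return a `fit_result`, identical to [fit_logistic()] on the same data.
#' @export
refit <- function(model, X, y, provenance = model$provenance) {
  fit_logistic(X, y, provenance = provenance)
}

#' Serialize a prediction model to flat JSON text
#'
#' Round-trips are bit-faithful for doubles: numerics are written with 17
#' significant digits, enough to reconstruct any IEEE-754 double exactly.
#'
#' @param model a `pred_model`.
#' @param path file path.
#' @return `read_pred_model` returns a `pred_model`; `write_pred_model`
#'   returns `path` invisibly.
#' @export
write_pred_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    coefficient_names = names(model$coefficients),
    coefficients = num(unname(model$coefficients)),
    chain = lapply(model$chain, num),
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pred_model
#' @export
read_pred_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(as.numeric(obj$coefficients), obj$coefficient_names)
  ch <- obj$chain
  chain <- if (is.matrix(ch)) lapply(seq_len(nrow(ch)), function(i) as.numeric(ch[i, ]))
           else if (length(ch)) lapply(ch, as.numeric)
           else list()
  prov <- if (is.null(obj$provenance)) list() else as.list(obj$provenance)
  pred_model(beta, chain = chain, provenance = prov)
}
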