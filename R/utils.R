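#' @keywords internal
"_PACKAGE"

# logit/inverse-logit on the natural scale used throughout
logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

# clip probabilities away from 0/1 before logit transforms; returns the
# clipped vector with an attribute recording how many values were clipped
clip_prob <- function(p, eps = 1e-12) {
  n_clipped <- sum(p < eps | p > 1 - eps)
  out <- pmin(pmax(p, eps), 1 - eps)
  attr(out, "n_clipped") <- n_clipped
  out
}

# Deterministic small-integer stream derived from a parent seed and an index,
# kept strictly below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, index) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime; multiplicative hash stays well mixed)
  s <- (as.double(seed) %% m + 1) * 48271 %% m
  as.integer((s + (as.double(index) + 1) * 69621) %% m)
}

# Stable string hash for labelled seeds (experiment cells / replicates).
hash_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  m <- 2147483647
  h <- as.double(seed) %% m
  for (k in codes) h <- (h * 31 + k) %% m
  as.integer(h)
}

# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_binary_outcome <- function(y) {
  if (length(y) == 0L) stop("outcome vector is empty", call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be coded 0/1 with no missing values", call. = FALSE)
  invisible(y)
}
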