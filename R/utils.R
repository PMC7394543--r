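# Internal helpers shared across modules.

# Evaluate an expression under a local RNG state so package functions that
# accept `seed` never disturb the caller's .Random.seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 16807) %% 2147483629
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

is_correlation_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < tol &&
    max(abs(diag(m) - 1)) < tol &&
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > -tol
}

# Lower-triangular factor usable for sampling from a correlation matrix that
# may be rank-deficient (e.g. unit correlation between traits).
safe_chol_factor <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  val <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(val), nrow = length(val))
}
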