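#' @keywords internal
"_PACKAGE"

## Internal numerical helpers shared across modules.

# Moore-Penrose pseudoinverse via SVD with a relative singular-value cutoff.
# Singular values below tol * sigma_max are treated as zero.
pinv <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  s <- svd(A)
  keep <- s$d > tol * s$d[1L]
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
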