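## Dynamic mode decomposition of trait-by-time matrices.
##
## A genotype's phenome snapshot x_t (p traits) is modelled as a linear
## time-invariant system x_{t+1} = A x_t. Exact DMD recovers the least-squares
## A from the shifted data pair (X1, X2); the Schur variant projects onto the
## leading r POD directions and factors the reduced operator through a real
## Schur decomposition, A_r = Phi R pinv(Phi), whose entries (R, Phi) serve as
## pseudo-traits for genomic prediction.

#' Build the shifted data pair for DMD
#'
#' Splits a trait-by-time matrix `X` into `X1` (columns 1..T-1) and `X2`
#' (columns 2..T), dropping every transition that straddles a measurement
#' gap so that all retained column pairs represent a single-day interval.
#'
#' @param X numeric matrix, traits in rows, time points in columns.
#' @param gap_after integer vector of time indices `t` such that the
#'   transition `t -> t+1` spans a multi-day gap and must be excluded.
#' @return An object of class `shifted_pair`: list with `X1`, `X2`
#'   (p x m matrices, m <= T-1) and `kept_transitions`, an m x 2 matrix of
#'   retained `(t, t+1)` index pairs in time order.
#' @export
build_shifted_pair <- function(X, gap_after = integer(0)) {
  X <- as.matrix(X)
  T_ <- ncol(X)
  if (T_ < 2L) stopf("need at least 2 time points, got %d", T_)
  gap_after <- as.integer(gap_after)
  if (length(gap_after) && (any(gap_after < 1L) || any(gap_after >= T_))) {
    stopf("gap_after indices must lie in 1..%d", T_ - 1L)
  }
  keep <- setdiff(seq_len(T_ - 1L), gap_after)
  if (!length(keep)) stopf("all %d transitions are excluded by gaps", T_ - 1L)
  structure(
    list(
      X1 = X[, keep, drop = FALSE],
      X2 = X[, keep + 1L, drop = FALSE],
      kept_transitions = cbind(t = keep, t_next = keep + 1L)
    ),
    class = "shifted_pair"
  )
}

#' Exact dynamic mode decomposition
#'
#' Returns the least-squares linear operator `A = X2 %*% pinv(X1)`, the
#' minimizer of the Frobenius misfit between `X2` and `A %*% X1`.
#'
#' @param pair a [build_shifted_pair()] result.
#' @return p x p numeric operator matrix.
#' @export
exact_dmd <- function(pair) {
  stopifnot(inherits(pair, "shifted_pair"))
  pair$X2 %*% pinv(pair$X1)
}

## --- ordered real Schur decomposition -------------------------------------

# Locate diagonal blocks of a real quasi-upper-triangular matrix.
# Returns integer vector of block start indices; a block is 2x2 when the
# subdiagonal entry below its start is (numerically) nonzero.
schur_blocks <- function(T_, tol) {
  n <- nrow(T_)
  starts <- integer(0)
  i <- 1L
  while (i <= n) {
    starts <- c(starts, i)
    if (i < n && abs(T_[i + 1L, i]) > tol) i <- i + 2L else i <- i + 1L
  }
  starts
}

# Swap two adjacent diagonal blocks of a real Schur form via the standard
# Sylvester-equation construction, updating Q in place. `i` is the start of
# the first block, `p`, `q` the two block sizes.
swap_schur_blocks <- function(Q, T_, i, p, q) {
  i1 <- i:(i + p - 1L)
  i2 <- (i + p):(i + p + q - 1L)
  T11 <- T_[i1, i1, drop = FALSE]
  T22 <- T_[i2, i2, drop = FALSE]
  T12 <- T_[i1, i2, drop = FALSE]
  # Solve T11 X - X T22 = T12 (vec form via Kronecker products).
  K <- kronecker(diag(q), T11) - kronecker(t(T22), diag(p))
  Xs <- matrix(solve(K, as.vector(T12)), p, q)
  G <- qr.Q(qr(rbind(-Xs, diag(q))), complete = TRUE)
  idx <- i:(i + p + q - 1L)
  T_[idx, ] <- t(G) %*% T_[idx, , drop = FALSE]
  T_[, idx] <- T_[, idx, drop = FALSE] %*% G
  Q[, idx] <- Q[, idx, drop = FALSE] %*% G
  # Zero the decoupled corner the swap leaves as round-off.
  T_[(i + q):(i + p + q - 1L), i:(i + q - 1L)] <- 0
  list(Q = Q, T = T_)
}

# Real Schur decomposition A = Q T t(Q) with diagonal blocks sorted by
# decreasing eigenvalue modulus and Q columns sign-fixed (largest-magnitude
# entry positive). Deterministic for a given A.
schur_ordered <- function(A, tol = NULL) {
  n <- nrow(A)
  if (n == 1L) return(list(Q = matrix(1, 1, 1), T = A))
  s <- Matrix::Schur(as.matrix(A))
  Q <- as.matrix(s$Q)
  T_ <- as.matrix(s$T)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(T_)))
  T_[lower.tri(T_)][abs(T_[lower.tri(T_)]) <= tol] <- 0
  # Bubble-sort adjacent blocks by decreasing modulus of their eigenvalues.
  repeat {
    starts <- schur_blocks(T_, tol)
    sizes <- diff(c(starts, n + 1L))
    mods <- vapply(seq_along(starts), function(b) {
      idx <- starts[b]:(starts[b] + sizes[b] - 1L)
      max(Mod(eigen(T_[idx, idx, drop = FALSE], only.values = TRUE)$values))
    }, numeric(1))
    swapped <- FALSE
    for (b in seq_len(length(starts) - 1L)) {
      if (mods[b + 1L] > mods[b] + tol) {
        res <- swap_schur_blocks(Q, T_, starts[b], sizes[b], sizes[b + 1L])
        Q <- res$Q; T_ <- res$T
        swapped <- TRUE
        break
      }
    }
    if (!swapped) break
  }
  # Sign convention: each Q column's largest-magnitude entry positive.
  flip <- vapply(seq_len(n), function(j) {
    v <- Q[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  if (any(flip)) {
    D <- diag(ifelse(flip, -1, 1), n)
    Q <- Q %*% D
    T_ <- D %*% T_ %*% D
  }
  list(Q = Q, T = T_)
}

#' Schur-based rank-reduced dynamic mode decomposition
#'
#' Executes the Schur-DMD factorization of a shifted pair: SVD of `X1`
#' truncated to rank `r`, POD projection `A_tilde = t(U_r) X2 V_r / sigma_r`,
#' real Schur decomposition `A_tilde = Q R t(Q)` with eigenvalue blocks
#' ordered by decreasing modulus, projected modes `Phi = X2 V_r sigma_r^-1 Q`
#' and operator reconstruction `A_r = Phi R pinv(Phi)`.
#'
#' Deterministic conventions make the components comparable across genotypes:
#' each column of `U` (and of `Q`) is flipped so its largest-magnitude entry
#' is positive (with `V`, `R` adjusted accordingly), and Schur blocks are
#' sorted by decreasing eigenvalue modulus.
#'
#' @param pair a [build_shifted_pair()] result.
#' @param r truncation rank, `1 <= r <= min(p, m)`; the r-th singular value
#'   of `X1` must be positive.
#' @return Object of class `schur_dmd`: list with `U_r`, `Sigma_r`, `V_r`,
#'   `A_tilde`, `Q`, `R`, `Phi`, `A_r`, `r` and `variance_retained`
#'   (fraction of squared singular value mass kept by the truncation).
#' @export
schur_dmd <- function(pair, r) {
  stopifnot(inherits(pair, "shifted_pair"))
  X1 <- pair$X1
  X2 <- pair$X2
  r <- check_count(r, "r")
  if (r > min(dim(X1))) {
    stopf("r = %d exceeds min(dim(X1)) = %d", r, min(dim(X1)))
  }
  s <- svd(X1)
  if (s$d[r] <= 1e-12 * s$d[1L]) {
    stopf("X1 is rank-deficient at r = %d (sigma_r ~ 0); use a smaller r", r)
  }
  # Sign convention: largest-magnitude entry of each left singular vector > 0.
  for (j in seq_len(r)) {
    v <- s$u[, j]
    if (v[which.max(abs(v))] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  U_r <- s$u[, seq_len(r), drop = FALSE]
  V_r <- s$v[, seq_len(r), drop = FALSE]
  d_r <- s$d[seq_len(r)]
  P <- X2 %*% V_r %*% diag(1 / d_r, r)   # = X2 V_r Sigma_r^{-1}
  A_tilde <- t(U_r) %*% P
  sc <- schur_ordered(A_tilde)
  Phi <- P %*% sc$Q
  A_r <- Phi %*% sc$T %*% pinv(Phi)
  structure(
    list(
      U_r = U_r,
      Sigma_r = diag(d_r, r),
      V_r = V_r,
      A_tilde = A_tilde,
      Q = sc$Q,
      R = sc$T,
      Phi = Phi,
      A_r = A_r,
      r = r,
      variance_retained = sum(d_r^2) / sum(s$d^2)
    ),
    class = "schur_dmd"
  )
}

#' Minimum number of structurally zero entries in the Schur factor R
#'
#' For a real quasi-upper-triangular r x r Schur factor, the count of
#' guaranteed zeros below the (block) diagonal: `r(r-2)/2` for even `r`,
#' `(r-1)^2/2` for odd `r`.
#'
#' @param r truncation rank (>= 1).
#' @return integer count of guaranteed zeros.
#' @export
guaranteed_zero_count <- function(r) {
  r <- check_count(r, "r")
  if (r %% 2L == 0L) r * (r - 2L) / 2L else (r - 1L)^2 / 2L
}

#' Reconstruct the low-rank operator from its building blocks
#'
#' `A_r = Phi %*% R %*% pinv(Phi)`; used both inside [schur_dmd()] and to
#' assemble operators from genomically predicted `R` and `Phi` entries.
#'
#' @param Phi p x r mode matrix.
#' @param R r x r quasi-upper-triangular factor.
#' @return p x p operator of rank at most r.
#' @export
reconstruct_operator <- function(Phi, R) {
  Phi <- as.matrix(Phi)
  R <- as.matrix(R)
  if (ncol(Phi) != nrow(R) || nrow(R) != ncol(R)) {
    stopf("shape mismatch: Phi is %dx%d, R is %dx%d",
          nrow(Phi), ncol(Phi), nrow(R), ncol(R))
  }
  Phi %*% R %*% pinv(Phi)
}

#' Propagate trait states with a linear operator
#'
#' Generates predicted trait states for `steps` consecutive time points.
#' In `recursive` mode the prediction at each step is fed forward from
#' `x_init`; in `iterative` mode each step starts from the observed state at
#' the preceding time point (column `t` of `observed`). One application of
#' `A` models a single-day interval; `elapsed` gives the number of modeled
#' days per step (e.g. 3 across a two-day measurement gap), bridged by
#' repeated application of `A`.
#'
#' @param A p x p operator.
#' @param x_init length-p state at the time point preceding the first
#'   prediction (used in recursive mode).
#' @param steps number of time points to predict.
#' @param mode `"recursive"` or `"iterative"`.
#' @param observed p x steps matrix of observed states at the preceding time
#'   points (required in iterative mode; column t seeds prediction t).
#' @param elapsed integer vector (length `steps`) of modeled days per step;
#'   defaults to all 1.
#' @return p x steps matrix of predicted states.
#' @export
propagate <- function(A, x_init, steps, mode = c("recursive", "iterative"),
                      observed = NULL, elapsed = NULL) {
  mode <- match.arg(mode)
  steps <- check_count(steps, "steps")
  A <- as.matrix(A)
  p <- nrow(A)
  if (is.null(elapsed)) elapsed <- rep(1L, steps)
  if (length(elapsed) != steps) stopf("elapsed must have length %d", steps)
  if (mode == "iterative") {
    if (is.null(observed)) {
      stopf("iterative propagation requires 'observed' states")
    }
    observed <- as.matrix(observed)
    if (nrow(observed) != p || ncol(observed) < steps) {
      stopf("'observed' must be %d x %d", p, steps)
    }
  }
  out <- matrix(NA_real_, p, steps)
  x <- as.numeric(x_init)
  for (t in seq_len(steps)) {
    from <- if (mode == "iterative") observed[, t] else x
    for (k in seq_len(elapsed[t])) from <- A %*% from
    out[, t] <- from
    x <- out[, t]
  }
  out
}
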