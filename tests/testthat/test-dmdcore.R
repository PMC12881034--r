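test_that("shifted pairs drop gap-straddling transitions", {
  X <- matrix(rnorm(3 * 25), 3, 25)
  pr <- build_shifted_pair(X, c(5, 10, 15, 20))
  expect_equal(ncol(pr$X1), 20L)   # 24 naive transitions minus 4 gaps
  expect_equal(ncol(pr$X2), 20L)
  expect_false(any(pr$kept_transitions[, 1] %in% c(5, 10, 15, 20)))
  expect_equal(pr$X2[, 1], X[, 2])
  pr2 <- build_shifted_pair(X[, 1:3, drop = FALSE])
  expect_equal(pr2$kept_transitions[, 1], c(1L, 2L))
  expect_error(build_shifted_pair(X[, 1:2], gap_after = 1), "excluded")
})

test_that("exact DMD recovers operators and is least-squares optimal", {
  X <- diag(4)
  A0 <- matrix(rnorm(16), 4)
  pr <- structure(list(X1 = X, X2 = A0 %*% X,
                       kept_transitions = cbind(1:4, 2:5)),
                  class = "shifted_pair")
  expect_equal(exact_dmd(pr), A0, tolerance = 1e-12)
  # X2 = X1 full row rank -> identity
  X1 <- matrix(rnorm(3 * 7), 3)
  prI <- structure(list(X1 = X1, X2 = X1,
                        kept_transitions = cbind(1:7, 2:8)),
                   class = "shifted_pair")
  expect_equal(exact_dmd(prI), diag(3), tolerance = 1e-10)
  # construct-and-recover from a noiseless trajectory
  A0 <- random_stable_operator(3, seed = 4)
  X <- linear_traj(A0, rnorm(3), 8)
  A <- exact_dmd(build_shifted_pair(X))
  expect_lt(max(abs(A - A0)), 1e-8)
  # optimality against random perturbations
  set.seed(5)
  pr <- build_shifted_pair(matrix(rnorm(3 * 10), 3))
  A <- exact_dmd(pr)
  base <- norm(pr$X2 - A %*% pr$X1, "F")
  for (i in 1:25) {
    B <- A + matrix(rnorm(9, sd = 0.1), 3)
    expect_gte(norm(pr$X2 - B %*% pr$X1, "F"), base)
  }
})

test_that("Schur-DMD components satisfy their structural contracts", {
  set.seed(6)
  X <- matrix(rnorm(50 * 12), 50, 12)
  pr <- build_shifted_pair(X)
  comp <- schur_dmd(pr, 2)
  expect_equal(dim(comp$Phi), c(50L, 2L))
  expect_equal(dim(comp$R), c(2L, 2L))
  expect_lt(max(abs(crossprod(comp$Q) - diag(2))), 1e-8)
  ev_R <- sort(Mod(eigen(comp$R, only.values = TRUE)$values))
  ev_A <- sort(Mod(eigen(comp$A_tilde, only.values = TRUE)$values))
  expect_lt(max(abs(ev_R - ev_A)), 1e-8)
  expect_equal(comp$A_r,
               comp$Phi %*% comp$R %*% longigp:::pinv(comp$Phi),
               tolerance = 1e-10)
  expect_lte(qr(comp$A_r)$rank, 2L)
  expect_true(all(abs(comp$R[row(comp$R) > col(comp$R) + 1]) == 0))
  # eigenvalue blocks sorted by decreasing modulus
  ev <- eigen(comp$R, only.values = TRUE)$values
  expect_true(all(diff(round(Mod(ev), 8)) <= 1e-8))
})

test_that("full-rank Schur-DMD reproduces exact DMD's action", {
  A0 <- random_stable_operator(4, seed = 7)
  X <- linear_traj(A0, rnorm(4), 10)
  pr <- build_shifted_pair(X)
  comp <- schur_dmd(pr, 4)
  expect_lt(max(abs(comp$A_r %*% pr$X1 - pr$X2)), 1e-8)
  # truncation monotonicity; variance retained hits 1 at full rank
  vr <- vapply(1:4, function(r) schur_dmd(pr, r)$variance_retained,
               numeric(1))
  expect_true(all(diff(vr) >= -1e-12))
  expect_equal(vr[4], 1)
  # rank-deficiency error
  Xlow <- linear_traj(diag(c(1, 0.5, 0, 0)), c(1, 1, 0, 0), 8)
  expect_error(schur_dmd(build_shifted_pair(Xlow), 4), "rank-deficient")
  # real input -> real components, including complex-pair cases
  rot <- 0.95 * matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2)
  Xr <- linear_traj(rot, c(1, 0), 12)
  cr <- schur_dmd(build_shifted_pair(Xr), 2)
  expect_true(all(vapply(cr[c("Phi", "R", "A_r", "Q")],
                         function(m) all(is.finite(m)) && is.numeric(m),
                         logical(1))))
  expect_lt(max(abs(cr$A_r - rot)), 1e-8)
})

test_that("guaranteed zero counts follow the parity formula", {
  expect_identical(vapply(1:6, guaranteed_zero_count, numeric(1)),
                   c(0, 0, 2, 4, 8, 12))
  expect_error(guaranteed_zero_count(0), "r")
})

test_that("reconstruct_operator matches its definition", {
  set.seed(8)
  Phi <- qr.Q(qr(matrix(rnorm(15), 5, 3)))
  expect_equal(reconstruct_operator(Phi, diag(3)), Phi %*% t(Phi),
               tolerance = 1e-10)
  Phi2 <- matrix(rnorm(10), 5, 2)
  A <- reconstruct_operator(Phi2, matrix(rnorm(4), 2))
  expect_equal(qr(A)$rank, 2L)
  expect_error(reconstruct_operator(Phi2, diag(3)), "shape")
})

test_that("propagation handles both modes and gap bridging", {
  expect_equal(propagate(diag(2), c(3, -1), 4),
               matrix(c(3, -1), 2, 4))
  expect_equal(propagate(2 * diag(2), c(1, 1), 3)[1, ], c(2, 4, 8))
  expect_error(propagate(diag(2), c(1, 1), 3, mode = "iterative"),
               "observed")
  # iterative restarts from the observed state each step
  A <- matrix(c(0.9, 0, 0.1, 0.8), 2)
  obs <- matrix(rnorm(2 * 5), 2, 5)
  it <- propagate(A, obs[, 1], 5, mode = "iterative", observed = obs)
  expect_equal(it[, 3], as.numeric(A %*% obs[, 3]))
  # elapsed > 1 applies the operator repeatedly
  rec <- propagate(A, c(1, 1), 2, elapsed = c(1, 3))
  expect_equal(rec[, 2], as.numeric(A %*% A %*% A %*% rec[, 1]))
  # generator oracle: recursive propagation of the true operator
  # reproduces the generated trajectory through the gaps
  g <- test_geno(6, 50)
  sim <- test_sim(g, p = 4, T_ = 12, normalize = "none", seed = 3)
  el <- longigp:::panel_elapsed(sim$panel)
  for (gi in 1:3) {
    X <- sim$panel$values[gi, , ]
    out <- propagate(sim$truth$A[, , gi], X[, 1], 11, elapsed = el)
    expect_lt(max(abs(out - X[, 2:12])), 1e-8)
  }
})
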