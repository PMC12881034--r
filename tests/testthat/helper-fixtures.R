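# Shared fixtures, all generated in code.

# Small population reused across tests.
test_geno <- function(n = 60, m = 200, seed = 42) {
  simulate_genotypes(n, m, maf_min = 0.05, seed = seed)
}

# Subset a genotype_matrix by line index.
sub_geno <- function(geno, idx) {
  geno$dosages <- geno$dosages[idx, , drop = FALSE]
  geno$line_ids <- geno$line_ids[idx]
  geno
}

# Noiseless exactly-linear panel (scale-only normalization keeps the
# dynamics linear).
test_sim <- function(geno, p = 5, T_ = 15, r = 2, h2 = 1, seed = 7,
                     normalize = "range", ...) {
  simulate_dynamic_phenome(geno, p = p, T_ = T_, r = r, h2 = h2,
                           seed = seed, normalize = normalize, ...)
}

# A trajectory generated by a known operator, plus its shifted pair.
linear_traj <- function(A, x1, T_) {
  p <- nrow(A)
  X <- matrix(0, p, T_)
  X[, 1] <- x1
  for (t in 2:T_) X[, t] <- A %*% X[, t - 1]
  X
}

random_stable_operator <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  A / (1.05 * max(Mod(eigen(A, only.values = TRUE)$values)))
}
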