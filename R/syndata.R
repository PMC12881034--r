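## Synthetic data with known ground truth.
##
## The generator emulates a MAGIC-type population of recombinant inbred
## lines: founder-mosaic genotypes with realistic linkage blocks, and
## multi-trait longitudinal phenotypes driven by genotype-specific low-rank
## linear dynamics whose building blocks (entries of the Schur factor R and
## the mode matrix Phi) are under additive marker control with known
## per-pseudo-trait heritability.

#' Simulate a MAGIC-like inbred genotype matrix
#'
#' Lines are recombinant mosaics of founder haplotypes laid out on
#' chromosomes, giving linkage-disequilibrium block structure typical of a
#' multi-parent RIL population. Dosages are homozygous (0/2). Markers whose
#' realized minor allele frequency falls below `maf_min` are re-drawn at the
#' founder level until the whole panel passes the threshold.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param n_markers number of biallelic markers.
#' @param maf_min minimum realized minor allele frequency, in (0, 0.5).
#' @param seed integer RNG seed; identical seeds give identical matrices.
#' @param n_founders number of founder haplotypes (default 9).
#' @param n_chrom number of chromosomes the markers are spread over.
#' @param crossovers expected crossovers per chromosome per line.
#' @return Object of class `genotype_matrix`: list with `dosages`
#'   (n_lines x n_markers, dimnames set), `line_ids`, `marker_ids`, `maf`.
#' @export
simulate_genotypes <- function(n_lines, n_markers, maf_min = 0.05, seed = 1L,
                               n_founders = 9L, n_chrom = 10L,
                               crossovers = 2) {
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  n_markers <- check_count(n_markers, "n_markers")
  if (!is.numeric(maf_min) || length(maf_min) != 1L ||
      maf_min <= 0 || maf_min >= 0.5) {
    stopf("maf_min must lie strictly between 0 and 0.5")
  }
  with_seed(seed, {
    n_chrom <- max(1L, min(n_chrom, n_markers))
    chrom <- sort(rep_len(seq_len(n_chrom), n_markers))
    # Founder alleles: guarantee each marker segregates among founders.
    draw_founder_alleles <- function(m) {
      n_alt <- sample(seq.int(2L, max(2L, n_founders - 2L)), m, replace = TRUE)
      vapply(n_alt, function(k) {
        a <- integer(n_founders)
        a[sample.int(n_founders, k)] <- 1L
        a
      }, integer(n_founders))   # n_founders x m
    }
    founder <- draw_founder_alleles(n_markers)
    # Founder mosaic per line and chromosome.
    mosaic <- matrix(0L, n_lines, n_markers)
    for (l in seq_len(n_lines)) {
      for (ch in seq_len(n_chrom)) {
        idx <- which(chrom == ch)
        m <- length(idx)
        p_sw <- min(1, crossovers / max(1L, m - 1L))
        f <- sample.int(n_founders, 1L)
        for (j in seq_len(m)) {
          if (j > 1L && stats::runif(1) < p_sw) f <- sample.int(n_founders, 1L)
          mosaic[l, idx[j]] <- f
        }
      }
    }
    allele <- matrix(founder[cbind(as.vector(mosaic),
                                   rep(seq_len(n_markers), each = n_lines))],
                     n_lines, n_markers)
    dos <- 2L * allele
    maf <- function(D) {
      f <- colMeans(D) / 2
      pmin(f, 1 - f)
    }
    # Re-draw founder allele patterns for markers failing the MAF floor.
    for (it in seq_len(200L)) {
      bad <- which(maf(dos) < maf_min)
      if (!length(bad)) break
      founder[, bad] <- draw_founder_alleles(length(bad))
      for (j in bad) {
        dos[, j] <- 2L * founder[cbind(mosaic[, j], rep(j, n_lines))]
      }
    }
    if (any(maf(dos) < maf_min)) {
      stopf("could not realize MAF >= %g for all markers", maf_min)
    }
    line_ids <- sprintf("L%03d", seq_len(n_lines))
    marker_ids <- sprintf("M%05d", seq_len(n_markers))
    dimnames(dos) <- list(line_ids, marker_ids)
    structure(
      list(dosages = dos, line_ids = line_ids, marker_ids = marker_ids,
           maf = stats::setNames(maf(dos), marker_ids), chrom = chrom),
      class = "genotype_matrix"
    )
  })
}

# Standardized column-centered marker matrix (internal).
scaled_markers <- function(geno) {
  W <- scale(geno$dosages)
  W[, attr(W, "scaled:scale") == 0] <- 0
  W[is.na(W)] <- 0
  W
}

# One standardized marker-additive component from a random QTL subset.
additive_component <- function(W, n_qtl) {
  qtl <- sample.int(ncol(W), min(n_qtl, ncol(W)))
  beta <- stats::rnorm(length(qtl))
  gv <- as.numeric(W[, qtl, drop = FALSE] %*% beta)
  s <- stats::sd(gv)
  if (s < 1e-12) gv else (gv - mean(gv)) / s
}

#' Simulate correlated additive traits for GP unit tests
#'
#' Genetic values are mixtures of independent marker-additive components
#' (disjoint QTL sets), mixed through the Cholesky factor of `genetic_corr`
#' so that pairwise genetic-value correlations match the target up to
#' sampling error; environmental noise is scaled per trait to the target
#' heritability.
#'
#' @param geno a [simulate_genotypes()] result.
#' @param n_traits number of traits.
#' @param h2 per-trait heritability in \[0, 1\] (recycled).
#' @param genetic_corr positive semidefinite n_traits x n_traits genetic
#'   correlation matrix (default identity).
#' @param seed RNG seed.
#' @param n_qtl QTL per underlying component.
#' @return list with `values` and `genetic_values` (n_lines x n_traits
#'   matrices) and `h2` (targets as used).
#' @export
simulate_additive_traits <- function(geno, n_traits, h2 = 0.5,
                                     genetic_corr = NULL, seed = 1L,
                                     n_qtl = 100L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n_traits <- check_count(n_traits, "n_traits")
  h2 <- rep_len(h2, n_traits)
  if (any(h2 < 0 | h2 > 1)) stopf("h2 entries must lie in [0, 1]")
  if (is.null(genetic_corr)) genetic_corr <- diag(n_traits)
  genetic_corr <- as.matrix(genetic_corr)
  if (!isTRUE(all.equal(dim(genetic_corr), c(n_traits, n_traits))) ||
      min(eigen(genetic_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stopf("genetic_corr must be a positive semidefinite %d x %d matrix",
          n_traits, n_traits)
  }
  with_seed(seed, {
    W <- scaled_markers(geno)
    n <- nrow(W)
    U <- vapply(seq_len(n_traits), function(j) additive_component(W, n_qtl),
                numeric(n))
    # In-sample Gram-Schmidt: components stay marker-additive (linear in
    # marker columns) but are exactly uncorrelated across lines, so the
    # Cholesky mixing realizes the target genetic correlations.
    for (j in seq_len(n_traits)) {
      if (j > 1L) {
        prev <- U[, seq_len(j - 1L), drop = FALSE]
        U[, j] <- U[, j] - prev %*% solve(crossprod(prev),
                                          crossprod(prev, U[, j]))
      }
      s <- stats::sd(U[, j])
      if (s > 1e-12) U[, j] <- (U[, j] - mean(U[, j])) / s
    }
    L <- chol(genetic_corr + 1e-10 * diag(n_traits))
    G <- U %*% L   # cov(G) = t(L) L = genetic_corr; unit variance per trait
    values <- G
    for (j in seq_len(n_traits)) {
      if (h2[j] == 0) {
        G[, j] <- 0
        values[, j] <- stats::rnorm(n)
      } else if (h2[j] < 1) {
        ve <- stats::var(G[, j]) * (1 - h2[j]) / h2[j]
        values[, j] <- G[, j] + stats::rnorm(n, sd = sqrt(ve))
      } else {
        values[, j] <- G[, j]
      }
    }
    rownames(values) <- rownames(G) <- geno$line_ids
    colnames(values) <- colnames(G) <- sprintf("trait%02d", seq_len(n_traits))
    list(values = values, genetic_values = G, h2 = h2)
  })
}

#' Realized heritability of a trait
#'
#' The ratio of genotypic to total variance, `var(g) / var(y)`.
#'
#' @param values observed trait values.
#' @param genetic_values genetic values of the same individuals.
#' @return realized heritability (a single number).
#' @export
realized_heritability <- function(values, genetic_values) {
  if (length(values) != length(genetic_values) || length(values) < 3L) {
    stopf("values and genetic_values must have equal length >= 3")
  }
  vt <- stats::var(values)
  if (vt < 1e-300) stopf("total variance is zero; heritability undefined")
  stats::var(genetic_values) / vt
}

# Day labels for T time points with `gap_days` unmeasured days after every
# `gap_period`-th point (internal).
time_grid <- function(T_, gap_period, gap_days) {
  labels <- numeric(T_)
  labels[1L] <- 1
  for (t in 2:T_) {
    step <- if (gap_period > 0L && (t - 1L) %% gap_period == 0L)
      1 + gap_days else 1
    labels[t] <- labels[t - 1L] + step
  }
  labels
}

#' Simulate a multi-trait longitudinal phenome with low-rank dynamics
#'
#' Each genotype's trait trajectory follows `x_{t+1} = A_g x_t` exactly
#' (one application of `A_g` per elapsed day; measurement gaps advance the
#' state by `1 + gap_days` days), where `A_g = Phi_g R_g pinv(Phi_g)` is a
#' rank-`r` operator. The free entries of the quasi-upper-triangular `R_g`
#' and of the mode matrix `Phi_g` — the pseudo-traits — are
#' marker-additive: population mean plus a genetic deviation (from `n_qtl`
#' QTL) plus an environmental deviation scaled to the target heritability.
#' Initial states are `x_1 = Phi_g c_g` with mildly heritable coordinates
#' `c_g`, so trajectories live exactly in the genotype's mode space.
#'
#' @param geno a [simulate_genotypes()] result.
#' @param p number of traits.
#' @param T_ number of time points (>= 3).
#' @param r dynamics rank (r <= p).
#' @param h2 target heritability per pseudo-trait in \[0, 1\] (recycled over
#'   the free entries: upper triangle of `R` row-major, then `Phi`
#'   column-wise).
#' @param noise_sd sd of additive observation noise on the measured values
#'   (does not propagate through the dynamics).
#' @param gap_period a `gap_days`-day measurement gap follows every
#'   `gap_period`-th time point (0 disables gaps).
#' @param gap_days unmeasured days per gap.
#' @param seed RNG seed.
#' @param normalize `"minmax"` (map each trait to \[0, 1\] across all
#'   genotypes and time points jointly), `"range"` (divide by the range
#'   only, preserving exact linearity of the dynamics) or `"none"`.
#' @param n_qtl QTL per pseudo-trait.
#' @return list with `panel` (class `phenotype_panel`) and `truth` (class
#'   `dynamics_truth`; per-genotype `A`, `R`, `Phi`, `x1`, pseudo-trait
#'   values and genetic values, target heritabilities, stabilization flags).
#' @export
simulate_dynamic_phenome <- function(geno, p, T_ = 25L, r = 2L, h2 = 0.9,
                                     noise_sd = 0, gap_period = 5L,
                                     gap_days = 2L, seed = 1L,
                                     normalize = c("minmax", "range", "none"),
                                     n_qtl = 50L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  normalize <- match.arg(normalize)
  p <- check_count(p, "p")
  T_ <- check_count(T_, "T_", min = 3L)
  r <- check_count(r, "r")
  if (r > p) stopf("r = %d must not exceed p = %d", r, p)
  n <- length(geno$line_ids)
  free_R <- which(upper.tri(matrix(0, r, r), diag = TRUE))  # column-major idx
  n_free <- length(free_R) + p * r
  h2 <- rep_len(h2, n_free)
  if (any(h2 < 0 | h2 > 1)) stopf("h2 entries must lie in [0, 1]")

  with_seed(seed, {
    W <- scaled_markers(geno)
    # Population-mean building blocks: separated stable eigenvalues on the
    # diagonal of an upper-triangular R, orthonormal mean modes.
    lams <- seq(0.99, max(0.80, 0.99 - 0.07 * (r - 1L)), length.out = r)
    R_bar <- diag(lams, r)
    if (r > 1L) R_bar[upper.tri(R_bar)] <- 0.05
    Phi_bar <- qr.Q(qr(matrix(stats::rnorm(p * r), p, r)))
    for (k in seq_len(r)) {
      if (Phi_bar[which.max(abs(Phi_bar[, k])), k] < 0)
        Phi_bar[, k] <- -Phi_bar[, k]
    }
    # Deviation scales: modest genotype-to-genotype variation around means.
    sd_R <- 0.02
    sd_Phi <- 0.05
    means <- c(R_bar[free_R], as.vector(Phi_bar))
    sds <- c(rep(sd_R, length(free_R)), rep(sd_Phi, p * r))
    # Pseudo-trait values: mean + sqrt(h2)*sd*standardized additive genetic
    # value + environmental residual.
    gvals <- matrix(0, n, n_free)
    pvals <- matrix(0, n, n_free)
    for (j in seq_len(n_free)) {
      g <- if (h2[j] > 0) additive_component(W, n_qtl) else numeric(n)
      gvals[, j] <- sqrt(h2[j]) * sds[j] * g
      env <- stats::rnorm(n, sd = sqrt(1 - h2[j]) * sds[j])
      pvals[, j] <- means[j] + gvals[, j] + env
    }
    # Initial-state coordinates: heritable around a fixed profile.
    c_bar <- seq(1, 0.4, length.out = r)
    Cmat <- vapply(seq_len(r), function(k) {
      c_bar[k] + 0.1 * (sqrt(0.5) * additive_component(W, n_qtl) +
                          sqrt(0.5) * stats::rnorm(n))
    }, numeric(n))

    gap_after <- if (gap_period > 0L) {
      g <- seq.int(gap_period, T_ - 1L, by = gap_period)
      g[g %% gap_period == 0L]
    } else integer(0)
    elapsed <- rep(1L, T_ - 1L)
    elapsed[gap_after] <- 1L + gap_days

    A_arr <- array(0, c(p, p, n))
    R_arr <- array(0, c(r, r, n))
    Phi_arr <- array(0, c(p, r, n))
    x1 <- matrix(0, p, n)
    stabilized <- logical(n)
    values <- array(0, c(n, p, T_))
    for (g_i in seq_len(n)) {
      R_g <- matrix(0, r, r)
      R_g[free_R] <- pvals[g_i, seq_along(free_R)]
      Phi_g <- matrix(pvals[g_i, -seq_along(free_R)], p, r)
      x <- as.numeric(Phi_g %*% Cmat[g_i, ])
      traj <- matrix(0, p, T_)
      traj[, 1L] <- x
      A_g <- Phi_g %*% R_g %*% pinv(Phi_g)
      for (t in seq_len(T_ - 1L)) {
        for (k in seq_len(elapsed[t])) x <- A_g %*% x
        traj[, t + 1L] <- x
      }
      if (any(!is.finite(traj)) || max(abs(traj)) > 1e6) {
        # Rescale eigenvalues into the unit disc and re-propagate.
        d <- diag(R_g)
        diag(R_g) <- sign(d) * pmin(abs(d), 1)
        A_g <- Phi_g %*% R_g %*% pinv(Phi_g)
        x <- as.numeric(Phi_g %*% Cmat[g_i, ])
        traj[, 1L] <- x
        for (t in seq_len(T_ - 1L)) {
          for (k in seq_len(elapsed[t])) x <- A_g %*% x
          traj[, t + 1L] <- x
        }
        stabilized[g_i] <- TRUE
        pvals[g_i, seq_along(free_R)] <- R_g[free_R]
      }
      A_arr[, , g_i] <- A_g
      R_arr[, , g_i] <- R_g
      Phi_arr[, , g_i] <- Phi_g
      x1[, g_i] <- traj[, 1L]
      values[g_i, , ] <- traj
    }
    if (noise_sd > 0) {
      values <- values + array(stats::rnorm(length(values), sd = noise_sd),
                               dim(values))
    }
    trait_ids <- sprintf("T%02d", seq_len(p))
    dimnames(values) <- list(geno$line_ids, trait_ids, NULL)
    panel <- new_phenotype_panel(values, trait_ids, time_grid(T_, gap_period,
                                                              gap_days),
                                 gap_after, gap_days)
    if (normalize != "none") panel <- normalize_panel(panel, normalize)

    free_R_rc <- arrayInd(free_R, c(r, r))
    pseudo_ids <- c(sprintf("R.%d.%d", free_R_rc[, 1], free_R_rc[, 2]),
                    sprintf("Phi.%d.%d", rep(seq_len(p), r),
                            rep(seq_len(r), each = p)))
    colnames(pvals) <- colnames(gvals) <- pseudo_ids
    rownames(pvals) <- rownames(gvals) <- geno$line_ids
    truth <- structure(
      list(A = A_arr, R = R_arr, Phi = Phi_arr, x1 = x1,
           pseudo_values = pvals, pseudo_genetic = gvals,
           h2 = stats::setNames(h2, pseudo_ids), stabilized = stabilized,
           elapsed = elapsed, r = r, p = p),
      class = "dynamics_truth"
    )
    list(panel = panel, truth = truth)
  })
}
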