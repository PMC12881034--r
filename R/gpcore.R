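## Genomic prediction engines.
##
## Single-trait ridge-regression BLUP (marker effects random with common
## variance), GRM-based GBLUP, and a latent-factor multi-trait model: the
## phenotype matrix is decomposed as Y = F Lambda + E and each latent
## factor (and residual column) is treated as an independent mixed model
## with a genomic random effect. The variance ratio lambda = sigma_e^2 /
## sigma_u^2 is estimated by restricted maximum likelihood through the
## spectral decomposition of the relationship kernel.

# REML for y = 1*mu + g + e, g ~ N(0, sigma_u^2 K), via eigen(K) (internal).
# Returns mu, lambda (= sigma_e^2/sigma_u^2), alpha = (K + lambda I)^-1 (y - mu)
# and the variance components.
kernel_reml <- function(eK, y, lambda = NULL) {
  n <- length(y)
  yt <- crossprod(eK$vectors, y)
  xt <- crossprod(eK$vectors, rep(1, n))
  d <- pmax(eK$values, 0)
  rll <- function(log_lam) {
    lam <- exp(log_lam)
    w <- 1 / (d + lam)
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    rss <- sum(w * (yt - xt * mu)^2)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(d + lam)) + log(sxx))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(rll, c(-12, 12), maximum = TRUE, tol = 1e-9)
    lambda <- exp(opt$maximum)
  }
  w <- 1 / (d + lambda)
  sxx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / sxx
  alpha <- eK$vectors %*% (w * (yt - xt * mu))
  s2u <- sum(w * (yt - xt * mu)^2) / (n - 1)
  list(mu = mu, lambda = lambda, alpha = as.numeric(alpha),
       sigma_u2 = s2u, sigma_e2 = lambda * s2u)
}

#' Fit a ridge-regression BLUP model
#'
#' Marker effects are random with a common variance; the ratio
#' `lambda = sigma_e^2 / sigma_u^2` is estimated by REML via the spectral
#' decomposition of the marker kernel `W t(W)` (centered dosages), and the
#' effects are the ridge solution at that lambda.
#'
#' @param geno training `genotype_matrix` (n_train >= 5 lines).
#' @param y numeric training phenotype, no missing values.
#' @param lambda optional fixed variance ratio (skips REML; test hook —
#'   `Inf` shrinks all predictions to the training mean).
#' @return Object of class `ridge_model`: `intercept`, `marker_effects`,
#'   `lambda`, `centering` (per-marker 2*p_j), `marker_ids`, `line_ids`.
#' @export
fit_rrblup <- function(geno, y, lambda = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- as.numeric(y)
  n <- nrow(geno$dosages)
  if (length(y) != n || anyNA(y)) stopf("y must be complete with length %d", n)
  if (n < 5L) stopf("need at least 5 training lines")
  if (stats::var(y) < 1e-300) stopf("zero phenotypic variance")
  ctr <- colMeans(geno$dosages)
  W <- sweep(geno$dosages, 2L, ctr)
  if (!is.null(lambda) && is.infinite(lambda)) {
    return(structure(
      list(intercept = mean(y),
           marker_effects = stats::setNames(numeric(ncol(W)),
                                            geno$marker_ids),
           lambda = Inf, marker_ids = geno$marker_ids,
           line_ids = geno$line_ids),
      class = "ridge_model"
    ))
  }
  K <- tcrossprod(W)
  fit <- kernel_reml(eigen(K, symmetric = TRUE), y, lambda = lambda)
  beta <- as.numeric(crossprod(W, fit$alpha))
  # Fold the marker centering into the intercept so that predictions are
  # simply intercept + dosages %*% effects.
  structure(
    list(intercept = fit$mu - sum(ctr * beta),
         marker_effects = stats::setNames(beta, geno$marker_ids),
         lambda = fit$lambda, marker_ids = geno$marker_ids,
         line_ids = geno$line_ids, sigma_u2 = fit$sigma_u2,
         sigma_e2 = fit$sigma_e2),
    class = "ridge_model"
  )
}

#' Predict phenotypes from a ridge model
#'
#' `intercept + (dosages - centering) %*% marker_effects`; test markers are
#' aligned to the training markers by id.
#'
#' @param model a [fit_rrblup()] result.
#' @param geno_test `genotype_matrix` with exactly the training markers.
#' @return named numeric vector of predictions.
#' @export
predict_rrblup <- function(model, geno_test) {
  stopifnot(inherits(model, "ridge_model"),
            inherits(geno_test, "genotype_matrix"))
  if (!setequal(model$marker_ids, geno_test$marker_ids)) {
    d1 <- setdiff(model$marker_ids, geno_test$marker_ids)
    d2 <- setdiff(geno_test$marker_ids, model$marker_ids)
    stopf("marker mismatch; missing from test: %s; extra in test: %s",
          paste(utils::head(d1, 5), collapse = ","),
          paste(utils::head(d2, 5), collapse = ","))
  }
  X <- geno_test$dosages[, model$marker_ids, drop = FALSE]
  stats::setNames(as.numeric(model$intercept + X %*% model$marker_effects),
                  geno_test$line_ids)
}

#' GBLUP: genetic-value prediction from a genomic relationship matrix
#'
#' Mixed-model prediction of genetic values for all lines, with the
#' variance ratio estimated by REML on the training block of the GRM.
#'
#' @param grm a [vanraden_grm()] result covering training and test lines.
#' @param y_train numeric phenotypes of the training lines.
#' @param train_idx indices (or line ids) of the training lines in the GRM.
#' @param lambda optional fixed variance ratio.
#' @return Object of class `gblup_model`: `predictions` (named vector over
#'   all GRM lines, `mu + g_hat`), `mu`, `lambda`, `sigma_u2`, `sigma_e2`.
#' @export
fit_gblup <- function(grm, y_train, train_idx, lambda = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (is.character(train_idx)) train_idx <- match(train_idx, grm$line_ids)
  y_train <- as.numeric(y_train)
  if (length(y_train) != length(train_idx) || anyNA(y_train)) {
    stopf("y_train must be complete and match train_idx")
  }
  G_tt <- grm$matrix[train_idx, train_idx, drop = FALSE]
  fit <- kernel_reml(eigen(G_tt, symmetric = TRUE), y_train, lambda = lambda)
  g_all <- as.numeric(grm$matrix[, train_idx, drop = FALSE] %*% fit$alpha)
  structure(
    list(predictions = stats::setNames(fit$mu + g_all, grm$line_ids),
         genetic_values = stats::setNames(g_all, grm$line_ids),
         mu = fit$mu, lambda = fit$lambda, sigma_u2 = fit$sigma_u2,
         sigma_e2 = fit$sigma_e2, train_idx = train_idx),
    class = "gblup_model"
  )
}

#' Number of latent factors for the multi-trait model
#'
#' `max(1, min(floor(n_train / 4), floor(t_cols / 2)))`.
#'
#' @param n_train number of training genotypes (>= 4).
#' @param t_cols number of model columns (>= 2).
#' @return integer factor count.
#' @export
choose_k <- function(n_train, t_cols) {
  n_train <- check_count(n_train, "n_train", min = 4L)
  t_cols <- check_count(t_cols, "t_cols", min = 2L)
  max(1L, min(n_train %/% 4L, t_cols %/% 2L))
}

#' Fit the latent-factor multi-trait genomic prediction model
#'
#' Two-level model: `Y = 1 beta + F Lambda + E`, with the latent scores
#' obtained by SVD-initialised alternating least squares (loadings by
#' column-wise regression given F, scores by ridge-regularized projection
#' given Lambda, iterated to a fixed tolerance on the training
#' reconstruction error), followed by an independent GRM mixed model per
#' factor column (REML variance split and BLUP of the genetic part) and
#' per-column residual variances.
#'
#' @param grm a `grm` covering at least the training lines.
#' @param Y_train n_train x t_cols numeric matrix, no missing cells;
#'   rownames identify the training lines in the GRM.
#' @param k number of latent factors (`k < n_train`); default
#'   [choose_k()] of the training dimensions.
#' @param max_iter,tol ALS stopping rule (relative reconstruction-error
#'   change below `tol`, or `max_iter` sweeps).
#' @return Object of class `factor_model`: `Lambda` (k x t), `F_train`,
#'   `beta`, `factor_fits` (per-factor GBLUP pieces: REML variance
#'   components and BLUP coefficients), `resid_var`, `k`, `train_ids`,
#'   `col_ids`, `recon_error` trace, and the training-kernel
#'   eigendecomposition `eK` reused at prediction time.
#' @export
fit_factor_mtgp <- function(grm, Y_train, k = NULL, max_iter = 500L,
                            tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  Y_train <- as.matrix(Y_train)
  if (anyNA(Y_train)) stopf("Y_train must have no missing cells")
  n <- nrow(Y_train)
  t_cols <- ncol(Y_train)
  if (is.null(k)) k <- choose_k(n, t_cols)
  k <- check_count(k, "k")
  if (k >= n) stopf("k = %d must be smaller than n_train = %d", k, n)
  train_ids <- rownames(Y_train)
  if (is.null(train_ids)) stopf("Y_train must carry line ids as rownames")
  train_idx <- match(train_ids, grm$line_ids)
  if (anyNA(train_idx)) stopf("training lines missing from the GRM")

  beta <- colMeans(Y_train)
  Yc <- sweep(Y_train, 2L, beta)
  sv <- svd(Yc, nu = k, nv = k)
  F_ <- sv$u %*% diag(sv$d[seq_len(k)], k)
  L <- t(sv$v)
  err <- sqrt(sum((Yc - F_ %*% L)^2))
  trace <- err
  ridge <- 1e-8
  for (it in seq_len(max_iter)) {
    L_new <- solve(crossprod(F_) + ridge * diag(k), crossprod(F_, Yc))
    F_new <- t(solve(tcrossprod(L_new) + ridge * diag(k), L_new %*% t(Yc)))
    new_err <- sqrt(sum((Yc - F_new %*% L_new)^2))
    if (new_err > err) break   # keep the error trace non-increasing
    L <- L_new
    F_ <- F_new
    trace <- c(trace, new_err)
    converged <- abs(err - new_err) <= tol * max(err, 1e-300)
    err <- new_err
    if (converged) break
  }
  E <- Yc - F_ %*% L
  resid_var <- pmax(colMeans(E^2), 1e-8)
  G_tt <- grm$matrix[train_idx, train_idx, drop = FALSE]
  eK <- eigen(G_tt, symmetric = TRUE)
  factor_fits <- lapply(seq_len(k), function(j) {
    if (stats::var(F_[, j]) < 1e-12) {
      return(list(mu = mean(F_[, j]), alpha = numeric(n), lambda = Inf,
                  sigma_u2 = 0, sigma_e2 = stats::var(F_[, j])))
    }
    kernel_reml(eK, F_[, j])
  })
  structure(
    list(Lambda = L, F_train = F_, beta = beta, factor_fits = factor_fits,
         resid_var = resid_var, k = k, train_ids = train_ids,
         train_idx = train_idx, col_ids = colnames(Y_train),
         recon_error = trace, eK = eK),
    class = "factor_model"
  )
}

#' Predict with the latent-factor model (CV1 or CV2)
#'
#' Without secondary observations (CV1), test-line factor scores are the
#' genomic BLUPs of the factor genetic values through the GRM. With
#' observed secondary columns (CV2), the scores are the Gaussian posterior
#' combination of that genomic prior — whose spread is the per-line
#' prediction error variance of the factor BLUP plus the factor residual
#' variance — with the regression of the observed secondary values on
#' their loadings, weighted by the inverse per-column residual variances.
#' Predictions are `beta + scores %*% Lambda`.
#'
#' @param model a [fit_factor_mtgp()] result.
#' @param grm the `grm` used at fit time (must cover the test lines).
#' @param test_idx indices or line ids of the test lines in the GRM.
#' @param secondary_obs optional list with `cols` (a strict subset of the
#'   model columns, by name or index) and `values` (n_test x length(cols)
#'   observed matrix).
#' @return n_test x t_cols matrix of predictions for all model columns
#'   (rownames = test line ids); callers select the focal columns.
#' @export
predict_factor_mtgp <- function(model, grm, test_idx, secondary_obs = NULL) {
  stopifnot(inherits(model, "factor_model"), inherits(grm, "grm"))
  if (is.character(test_idx)) test_idx <- match(test_idx, grm$line_ids)
  if (anyNA(test_idx)) stopf("test lines missing from the GRM")
  G_xt <- grm$matrix[test_idx, model$train_idx, drop = FALSE]
  F0 <- vapply(seq_len(model$k), function(j) {
    f <- model$factor_fits[[j]]
    f$mu + as.numeric(G_xt %*% f$alpha)
  }, numeric(length(test_idx)))
  F0 <- matrix(F0, nrow = length(test_idx))
  scores <- F0
  if (!is.null(secondary_obs)) {
    cols <- secondary_obs$cols
    if (is.character(cols)) cols <- match(cols, model$col_ids)
    if (anyNA(cols) || !length(cols) ||
        length(cols) >= length(model$col_ids)) {
      stopf("secondary columns must be a strict, known subset of the model columns")
    }
    Ys <- as.matrix(secondary_obs$values)
    if (nrow(Ys) != length(test_idx) || ncol(Ys) != length(cols)) {
      stopf("secondary values must be %d x %d", length(test_idx),
            length(cols))
    }
    Ls <- model$Lambda[, cols, drop = FALSE]          # k x s
    Dinv <- 1 / model$resid_var[cols]
    LDL <- Ls %*% (Dinv * t(Ls))
    Ysc <- sweep(Ys, 2L, model$beta[cols])
    proj <- Ls %*% (Dinv * t(Ysc))                    # k x n_test
    # Prior spread per line and factor: PEV of the genomic BLUP plus the
    # factor's non-genetic variance.
    B <- grm$matrix[test_idx, model$train_idx, drop = FALSE] %*%
      model$eK$vectors
    B2 <- B^2
    g_self <- diag(grm$matrix)[test_idx]
    tau2 <- vapply(seq_len(model$k), function(j) {
      f <- model$factor_fits[[j]]
      if (!is.finite(f$lambda)) return(rep(1e-8, length(test_idx)))
      w <- 1 / (pmax(model$eK$values, 0) + f$lambda)
      q <- as.numeric(B2 %*% w)
      pmax(f$sigma_u2 * (g_self - q) + f$sigma_e2, 1e-8)
    }, numeric(length(test_idx)))
    tau2 <- matrix(tau2, nrow = length(test_idx))
    scores <- F0
    for (i in seq_along(test_idx)) {
      P0inv <- diag(1 / tau2[i, ], model$k)
      scores[i, ] <- solve(P0inv + LDL,
                           P0inv %*% F0[i, ] + proj[, i, drop = FALSE])
    }
  }
  pred <- sweep(scores %*% model$Lambda, 2L, model$beta, `+`)
  rownames(pred) <- grm$line_ids[test_idx]
  colnames(pred) <- model$col_ids
  pred
}
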