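## Orchestration of the prediction scenarios over cross-validation plans.
##
## Scenarios: dynamicGP with a single-trait ridge core or a latent-factor
## multi-trait core (optionally with the initial phenotypic state as
## secondary traits), the direct configurations ST-STP (one single-trait
## model per trait-time pair), CV1 (one factor model over all trait-time
## columns, genomic data only), CV2.1 (initial time point as secondary
## traits for the whole series) and CV2.2 (the preceding time point as
## secondary traits, one model per transition), and CV3 forecasting of
## time points beyond the training window.

#' Build a cross-validation plan
#'
#' Random fold partitions, reproducibly derived from a master seed (one
#' fixed offset per iteration); fold sizes differ by at most one.
#'
#' @param line_ids character vector of line ids.
#' @param n_folds number of folds (>= 2, <= number of lines).
#' @param n_iterations number of independent partitions.
#' @param seed master seed.
#' @return Object of class `cv_plan`: `assignments` is an
#'   n_lines x n_iterations matrix of fold labels.
#' @export
make_cv_plan <- function(line_ids, n_folds = 5L, n_iterations = 20L,
                         seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  n_iterations <- check_count(n_iterations, "n_iterations")
  n <- length(line_ids)
  if (n_folds > n) stopf("n_folds = %d exceeds the %d lines", n_folds, n)
  assignments <- vapply(seq_len(n_iterations), function(it) {
    with_seed(seed + it, sample(rep_len(seq_len(n_folds), n)))
  }, integer(n))
  rownames(assignments) <- line_ids
  structure(
    list(line_ids = line_ids, n_folds = n_folds,
         n_iterations = n_iterations, assignments = assignments,
         seed = seed),
    class = "cv_plan"
  )
}

#' Extract population pseudo-traits from per-genotype Schur-DMD
#'
#' Decomposes each genotype's trait x time matrix (its own phenotypes
#' only) with [schur_dmd()] under the fixed sign and eigenvalue-ordering
#' conventions, pools the entries of `R` (row-major) and `Phi`
#' (column-wise per mode) into population-level pseudo-trait columns,
#' aligns each mode's sign against the population-mean mode, and flags
#' columns that are constant across the population (these must be excluded
#' from genomic prediction).
#'
#' @param panel a `phenotype_panel` (all genotypes share the time grid).
#' @param r truncation rank.
#' @return Object of class `pseudo_trait_table`: `values`
#'   (n_lines x (r^2 + p*r) matrix), `meta` (per column: matrix, row,
#'   col), `constant` flags, `components` (per-genotype `schur_dmd`
#'   objects after alignment), `r`, `p`.
#' @export
extract_pseudotraits <- function(panel, r) {
  stopifnot(inherits(panel, "phenotype_panel"))
  r <- check_count(r, "r")
  n <- dim(panel$values)[1L]
  p <- dim(panel$values)[2L]
  comps <- vector("list", n)
  for (g in seq_len(n)) {
    comps[[g]] <- tryCatch(
      schur_dmd(build_shifted_pair(panel$values[g, , ], panel$gap_after), r),
      error = function(e) {
        stopf("genotype '%s' failed the decomposition: %s",
              panel$line_ids[g], conditionMessage(e))
      }
    )
  }
  # Sign-align each mode against the population mean mode.
  Phi_mean <- Reduce(`+`, lapply(comps, `[[`, "Phi")) / n
  for (g in seq_len(n)) {
    flips <- rep(1, r)
    for (k in seq_len(r)) {
      cc <- suppressWarnings(stats::cor(comps[[g]]$Phi[, k], Phi_mean[, k]))
      if (is.finite(cc) && cc < 0) flips[k] <- -1
    }
    if (any(flips < 0)) {
      D <- diag(flips, r)
      comps[[g]]$Phi <- comps[[g]]$Phi %*% D
      comps[[g]]$Q <- comps[[g]]$Q %*% D
      comps[[g]]$R <- D %*% comps[[g]]$R %*% D
    }
  }
  vals <- t(vapply(comps, function(cm) {
    c(as.vector(t(cm$R)), as.vector(cm$Phi))
  }, numeric(r * r + p * r)))
  meta <- data.frame(
    matrix = c(rep("R", r * r), rep("Phi", p * r)),
    row = c(rep(seq_len(r), each = r), rep(seq_len(p), r)),
    col = c(rep(seq_len(r), r), rep(seq_len(r), each = p))
  )
  colnames(vals) <- paste0(meta$matrix, ".", meta$row, ".", meta$col)
  rownames(vals) <- panel$line_ids
  constant <- apply(vals, 2L, stats::sd) < 1e-10
  structure(
    list(values = vals, meta = meta, constant = constant,
         components = comps, r = r, p = p, line_ids = panel$line_ids),
    class = "pseudo_trait_table"
  )
}

# Marker kernel (or GRM fallback) for single-trait ridge cores (internal).
ridge_kernel <- function(geno, grm, line_ids) {
  if (!is.null(geno)) {
    W <- sweep(geno$dosages, 2L, colMeans(geno$dosages))
    K <- tcrossprod(W)
    dimnames(K) <- list(geno$line_ids, geno$line_ids)
  } else if (!is.null(grm)) {
    K <- grm$matrix
  } else {
    stopf("provide 'geno' or 'grm'")
  }
  K[line_ids, line_ids, drop = FALSE]
}

# Per-column kernel ridge over a fold: fit on train rows, predict test rows
# (internal). Returns n_test x n_cols matrix.
ridge_predict_cols <- function(K, Y, train, test) {
  eK <- eigen(K[train, train, drop = FALSE], symmetric = TRUE)
  K_xt <- K[test, train, drop = FALSE]
  out <- vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[train, j]
    if (stats::var(y) < 1e-12) return(rep(mean(y), length(test)))
    fit <- kernel_reml(eK, y)
    fit$mu + as.numeric(K_xt %*% fit$alpha)
  }, numeric(length(test)))
  matrix(out, nrow = length(test),
         dimnames = list(rownames(K)[test], colnames(Y)))
}

# Wide genotype x (trait, time) matrix of a panel (internal).
wide_panel <- function(panel) {
  d <- dim(panel$values)
  Y <- matrix(panel$values, d[1L], d[2L] * d[3L])
  meta <- data.frame(trait = rep(seq_len(d[2L]), d[3L]),
                     time = rep(seq_len(d[3L]), each = d[2L]))
  colnames(Y) <- sprintf("%s.t%02d", panel$trait_ids[meta$trait], meta$time)
  rownames(Y) <- panel$line_ids
  attr(Y, "meta") <- meta
  Y
}

new_prediction_set <- function(scenario, pred, predicted_times, plan,
                               bookkeeping) {
  structure(
    list(scenario = scenario, pred = pred,
         predicted_times = predicted_times, plan = plan,
         bookkeeping = bookkeeping),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction_set '%s': %d iteration(s), time points %s\n",
              x$scenario, length(x$pred),
              paste(range(x$predicted_times), collapse = "-")))
  invisible(x)
}

# Assemble an operator from (possibly partially predicted) pseudo-trait
# values and propagate one line (internal).
assemble_and_propagate <- function(pt_row, r, p, mode, x_init, steps,
                                   elapsed, observed = NULL) {
  R_hat <- matrix(pt_row[seq_len(r * r)], r, r, byrow = TRUE)
  Phi_hat <- matrix(pt_row[-seq_len(r * r)], p, r)
  A_hat <- reconstruct_operator(Phi_hat, R_hat)
  propagate(A_hat, x_init, steps, mode = mode, observed = observed,
            elapsed = elapsed)
}

# Factor-core fit + predict for one block of pseudo-trait columns,
# optionally with the initial phenotypic state as secondary traits
# (internal). Returns predictions for the block columns.
factor_block_predict <- function(grm, Y_block, train, test, tp1_train,
                                 tp1_test) {
  if (!is.null(tp1_train)) {
    sec_ids <- paste0("TP1.", colnames(tp1_train))
    Y_fit <- cbind(Y_block[train, , drop = FALSE], tp1_train[train, ])
    colnames(Y_fit) <- c(colnames(Y_block), sec_ids)
    k <- choose_k(length(train), ncol(Y_fit))
    fm <- fit_factor_mtgp(grm, Y_fit, k = k)
    pred <- predict_factor_mtgp(fm, grm, test,
                                secondary_obs = list(cols = sec_ids,
                                                     values = tp1_test))
    pred[, colnames(Y_block), drop = FALSE]
  } else {
    if (ncol(Y_block) < 2L) {
      # A single-column block degenerates to a per-column mixed model.
      pr <- ridge_predict_cols(grm$matrix, Y_block,
                               match(rownames(Y_block)[train],
                                     rownames(grm$matrix)),
                               match(rownames(Y_block)[test],
                                     rownames(grm$matrix)))
      return(pr)
    }
    k <- choose_k(length(train), ncol(Y_block))
    fm <- fit_factor_mtgp(grm, Y_block[train, , drop = FALSE], k = k)
    predict_factor_mtgp(fm, grm, test)
  }
}

#' Run dynamicGP over a cross-validation plan
#'
#' Per split: the pseudo-traits of the training lines (each derived solely
#' from that line's own phenotypes) are predicted for the test lines from
#' genomic data — one ridge model per pseudo-trait column
#' (`core = "rrblup"`) or `r + 1` latent-factor models (one for the `R`
#' entries, one per `Phi` mode; `core = "factor"`); predicted entries are
#' reassembled into a per-genotype operator and propagated from the true
#' initial state. Constant pseudo-trait columns are excluded from the GP
#' step and filled with their population value. With `include_tp1`, all
#' traits at t = 1 (training and test lines — already visible to
#' dynamicGP as the initial state) join the factor models as secondary
#' traits.
#'
#' @param panel a `phenotype_panel`.
#' @param geno a `genotype_matrix` (needed for the rrblup core).
#' @param grm a `grm` (needed for the factor core).
#' @param plan a [make_cv_plan()] result.
#' @param core `"rrblup"` or `"factor"`.
#' @param r truncation rank.
#' @param mode propagation mode, `"recursive"` or `"iterative"`.
#' @param include_tp1 add the initial phenotypic state as secondary traits
#'   (factor core only).
#' @param oracle test hook: bypass GP and use each test line's own
#'   extracted pseudo-traits.
#' @return a `prediction_set` over time points `2..T`.
#' @export
run_dynamicgp <- function(panel, geno = NULL, grm = NULL, plan,
                          core = c("rrblup", "factor"), r = 2L,
                          mode = c("recursive", "iterative"),
                          include_tp1 = FALSE, oracle = FALSE) {
  core <- match.arg(core)
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "phenotype_panel"), inherits(plan, "cv_plan"))
  if (core == "factor" && is.null(grm) && !oracle) {
    stopf("the factor core requires a GRM")
  }
  if (include_tp1 && core != "factor") {
    stopf("include_tp1 applies to the factor core")
  }
  d <- dim(panel$values)
  n <- d[1L]; p <- d[2L]; T_ <- d[3L]
  elapsed <- panel_elapsed(panel)
  pt <- extract_pseudotraits(panel, r)
  active <- which(!pt$constant)
  const_fill <- colMeans(pt$values)
  K <- if (core == "rrblup" && !oracle) {
    ridge_kernel(geno, grm, panel$line_ids)
  } else NULL
  tp1 <- panel$values[, , 1L]
  colnames(tp1) <- panel$trait_ids
  scenario <- paste0("dynGP-", substr(mode, 1, 4), "-", core,
                     if (include_tp1) "+TP1" else "")
  blocks <- c(list(R = intersect(which(pt$meta$matrix == "R"), active)),
              lapply(seq_len(r), function(k) {
                intersect(which(pt$meta$matrix == "Phi" &
                                  pt$meta$col == k), active)
              }))
  names(blocks)[-1L] <- paste0("Phi", seq_len(r))
  blocks <- Filter(length, blocks)
  preds <- vector("list", plan$n_iterations)
  for (it in seq_len(plan$n_iterations)) {
    arr <- array(NA_real_, d, dimnames = dimnames(panel$values))
    for (f in seq_len(plan$n_folds)) {
      test <- which(plan$assignments[, it] == f)
      train <- setdiff(seq_len(n), test)
      pt_hat <- matrix(rep(const_fill, each = length(test)),
                       length(test), ncol(pt$values),
                       dimnames = list(panel$line_ids[test],
                                       colnames(pt$values)))
      if (oracle) {
        pt_hat[, active] <- pt$values[test, active, drop = FALSE]
        audit_record(scenario, it, f, "oracle", panel$line_ids[test], 2:T_)
      } else if (core == "rrblup") {
        pt_hat[, active] <- ridge_predict_cols(
          K, pt$values[, active, drop = FALSE], train, test)
        audit_record(scenario, it, f, "rrblup-percolumn",
                     panel$line_ids[test], 2:T_)
      } else {
        for (b in names(blocks)) {
          cols <- blocks[[b]]
          pred_b <- factor_block_predict(
            grm, pt$values[, cols, drop = FALSE], train, test,
            tp1_train = if (include_tp1) tp1 else NULL,
            tp1_test = if (include_tp1) tp1[test, , drop = FALSE] else NULL)
          pt_hat[, cols] <- pred_b
          audit_record(scenario, it, f, paste0("factor-", b),
                       panel$line_ids[test], 2:T_,
                       entered_test_cells = if (include_tp1)
                         data.frame(line = rep(panel$line_ids[test], p),
                                    time = 1L) else NULL,
                       allowed_times = 1L)
        }
      }
      for (i in seq_along(test)) {
        g <- test[i]
        arr[g, , 2:T_] <- assemble_and_propagate(
          pt_hat[i, ], r, p, mode,
          x_init = panel$values[g, , 1L], steps = T_ - 1L,
          elapsed = elapsed,
          observed = if (mode == "iterative")
            panel$values[g, , seq_len(T_ - 1L)] else NULL)
      }
    }
    preds[[it]] <- arr
  }
  bk <- count_models(if (core == "factor") "dyn-factor" else "dyn-rr",
                     p = p, T_ = T_, r = r)
  bk$active_pseudo_columns <- length(active)
  new_prediction_set(scenario, preds, 2:T_, plan, bk)
}

#' Run the direct whole-series configurations (ST-STP and CV1)
#'
#' The panel is arranged as a genotype x (trait, time) wide matrix of
#' `p*T` columns. `core = "st-stp"` fits one single-trait model per
#' column; `core = "factor"` fits a single latent-factor model over all
#' columns with `k` from [choose_k()]. Genomic data only, no secondary
#' traits.
#'
#' @inheritParams run_dynamicgp
#' @param core `"st-stp"` or `"factor"`.
#' @return a `prediction_set` over time points `1..T`.
#' @export
run_cv1_wide <- function(panel, geno = NULL, grm = NULL, plan,
                         core = c("st-stp", "factor")) {
  core <- match.arg(core)
  stopifnot(inherits(panel, "phenotype_panel"), inherits(plan, "cv_plan"))
  d <- dim(panel$values)
  n <- d[1L]; T_ <- d[3L]
  Y <- wide_panel(panel)
  scenario <- if (core == "st-stp") "ST-STP" else "CV1-wide"
  K <- if (core == "st-stp") ridge_kernel(geno, grm, panel$line_ids) else NULL
  preds <- vector("list", plan$n_iterations)
  for (it in seq_len(plan$n_iterations)) {
    arr <- array(NA_real_, d, dimnames = dimnames(panel$values))
    for (f in seq_len(plan$n_folds)) {
      test <- which(plan$assignments[, it] == f)
      train <- setdiff(seq_len(n), test)
      pred <- if (core == "st-stp") {
        ridge_predict_cols(K, Y, train, test)
      } else {
        fm <- fit_factor_mtgp(grm, Y[train, , drop = FALSE],
                              k = choose_k(length(train), ncol(Y)))
        predict_factor_mtgp(fm, grm, test)
      }
      arr[test, , ] <- array(pred, c(length(test), d[2L], T_))
      audit_record(scenario, it, f, core, panel$line_ids[test], 1:T_)
    }
    preds[[it]] <- arr
  }
  new_prediction_set(scenario, preds, 1:T_, plan,
                     count_models(if (core == "st-stp") "st-stp" else "cv1",
                                  p = d[2L], T_ = T_, r = NA))
}

#' Run the CV2.1 configuration (initial time point as secondary traits)
#'
#' One latent-factor model per split over all `p*T` columns; the `p`
#' traits at t = 1, observed for the test lines, act as secondary traits
#' and the remaining `p*(T-1)` columns are focal.
#'
#' @inheritParams run_dynamicgp
#' @param withhold_secondary test hook: drop the secondary block, which
#'   must make the output identical to the CV1 factor configuration.
#' @return a `prediction_set` over time points `2..T`.
#' @export
run_cv2_recursive <- function(panel, grm, plan, withhold_secondary = FALSE) {
  stopifnot(inherits(panel, "phenotype_panel"), inherits(plan, "cv_plan"))
  d <- dim(panel$values)
  n <- d[1L]; p <- d[2L]; T_ <- d[3L]
  Y <- wide_panel(panel)
  meta <- attr(Y, "meta")
  sec_cols <- which(meta$time == 1L)
  preds <- vector("list", plan$n_iterations)
  for (it in seq_len(plan$n_iterations)) {
    arr <- array(NA_real_, d, dimnames = dimnames(panel$values))
    for (f in seq_len(plan$n_folds)) {
      test <- which(plan$assignments[, it] == f)
      train <- setdiff(seq_len(n), test)
      fm <- fit_factor_mtgp(grm, Y[train, , drop = FALSE],
                            k = choose_k(length(train), ncol(Y)))
      pred <- predict_factor_mtgp(
        fm, grm, test,
        secondary_obs = if (withhold_secondary) NULL else
          list(cols = sec_cols,
               values = Y[test, sec_cols, drop = FALSE]))
      arr[test, , ] <- array(pred, c(length(test), p, T_))
      arr[test, , 1L] <- NA_real_
      audit_record("CV2.1", it, f, "factor", panel$line_ids[test], 2:T_,
                   entered_test_cells = data.frame(
                     line = rep(panel$line_ids[test], p), time = 1L),
                   allowed_times = 1L)
    }
    preds[[it]] <- arr
  }
  new_prediction_set("CV2.1", preds, 2:T_, plan,
                     count_models("cv2.1", p = p, T_ = T_, r = NA))
}

#' Run the CV2.2 configuration (preceding time point as secondary traits)
#'
#' For each transition `t -> t+1` a latent-factor model over the `2p`
#' columns of the two time points is fit on the training lines; the test
#' lines' time-`t` block is observed as secondary traits and the time-
#' `t+1` block is predicted. `T - 1` models per split.
#'
#' @inheritParams run_dynamicgp
#' @return a `prediction_set` over time points `2..T`.
#' @export
run_cv2_iterative <- function(panel, grm, plan) {
  stopifnot(inherits(panel, "phenotype_panel"), inherits(plan, "cv_plan"))
  d <- dim(panel$values)
  n <- d[1L]; p <- d[2L]; T_ <- d[3L]
  preds <- vector("list", plan$n_iterations)
  for (it in seq_len(plan$n_iterations)) {
    arr <- array(NA_real_, d, dimnames = dimnames(panel$values))
    for (f in seq_len(plan$n_folds)) {
      test <- which(plan$assignments[, it] == f)
      train <- setdiff(seq_len(n), test)
      for (t in seq_len(T_ - 1L)) {
        Yt <- cbind(panel$values[, , t], panel$values[, , t + 1L])
        colnames(Yt) <- c(sprintf("%s.t%02d", panel$trait_ids, t),
                          sprintf("%s.t%02d", panel$trait_ids, t + 1L))
        rownames(Yt) <- panel$line_ids
        sec <- seq_len(p)
        fm <- fit_factor_mtgp(grm, Yt[train, , drop = FALSE],
                              k = choose_k(length(train), 2L * p))
        pred <- predict_factor_mtgp(
          fm, grm, test,
          secondary_obs = list(cols = sec,
                               values = Yt[test, sec, drop = FALSE]))
        arr[test, , t + 1L] <- pred[, p + seq_len(p), drop = FALSE]
        audit_record("CV2.2", it, f, sprintf("factor-t%02d", t),
                     panel$line_ids[test], 2:T_,
                     entered_test_cells = data.frame(
                       line = rep(panel$line_ids[test], p), time = t),
                     allowed_times = t)
      }
    }
    preds[[it]] <- arr
  }
  new_prediction_set("CV2.2", preds, 2:T_, plan,
                     count_models("cv2.2", p = p, T_ = T_, r = NA))
}

#' Forecast unseen time points with dynamicGP (CV3)
#'
#' Training uses only transitions inside `1..split_time`; propagation
#' starts from the true state at `split_time`. Genotypes are seen and time
#' points unseen: the GP step fits on all lines' training-window
#' pseudo-traits and predicts in-sample (pass `plan` for genotype
#' hold-out on top). In iterative mode the observed states at forecast
#' horizons seed each step (an evaluation-only availability). The static
#' configurations cannot forecast and are rejected.
#'
#' @inheritParams run_dynamicgp
#' @param split_time last training time point (`2 <= split_time < T`).
#' @param variant `"dyn-rr"`, `"dyn-factor"` or `"dyn-factor-tp1"`;
#'   static scenario names raise an error.
#' @param plan optional `cv_plan` for genotype hold-out.
#' @return a `prediction_set` over time points `split_time+1 .. T`.
#' @export
run_forecast <- function(panel, geno = NULL, grm = NULL, split_time,
                         variant = "dyn-rr", r = 2L,
                         mode = c("recursive", "iterative"), plan = NULL,
                         oracle = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "phenotype_panel"))
  if (variant %in% c("st-stp", "cv1", "cv2.1", "cv2.2")) {
    stopf("the static GP methods are not applicable to forecasting")
  }
  if (!variant %in% c("dyn-rr", "dyn-factor", "dyn-factor-tp1")) {
    stopf("unknown forecast variant '%s'", variant)
  }
  d <- dim(panel$values)
  n <- d[1L]; p <- d[2L]; T_ <- d[3L]
  split_time <- check_count(split_time, "split_time", min = 2L)
  if (split_time >= T_) stopf("split_time must be < T = %d", T_)
  win <- panel
  win$values <- panel$values[, , seq_len(split_time), drop = FALSE]
  win$time_labels <- panel$time_labels[seq_len(split_time)]
  win$gap_after <- panel$gap_after[panel$gap_after < split_time]
  pt <- extract_pseudotraits(win, r)
  active <- which(!pt$constant)
  const_fill <- colMeans(pt$values)
  horizon <- (split_time + 1L):T_
  elapsed_fc <- panel_elapsed(panel)[split_time:(T_ - 1L)]
  splits <- if (is.null(plan)) {
    list(list(train = seq_len(n), test = seq_len(n), it = 1L, f = 1L))
  } else {
    out <- list()
    for (it in seq_len(plan$n_iterations)) {
      for (f in seq_len(plan$n_folds)) {
        test <- which(plan$assignments[, it] == f)
        out[[length(out) + 1L]] <- list(train = setdiff(seq_len(n), test),
                                        test = test, it = it, f = f)
      }
    }
    out
  }
  n_it <- if (is.null(plan)) 1L else plan$n_iterations
  preds <- replicate(n_it, array(NA_real_, d,
                                 dimnames = dimnames(panel$values)),
                     simplify = FALSE)
  K <- if (variant == "dyn-rr" && !oracle) {
    ridge_kernel(geno, grm, panel$line_ids)
  } else NULL
  tp1 <- win$values[, , 1L]
  colnames(tp1) <- panel$trait_ids
  for (sp in splits) {
    train <- sp$train; test <- sp$test
    pt_hat <- matrix(rep(const_fill, each = length(test)),
                     length(test), ncol(pt$values),
                     dimnames = list(panel$line_ids[test],
                                     colnames(pt$values)))
    if (oracle) {
      pt_hat[, active] <- pt$values[test, active, drop = FALSE]
    } else if (variant == "dyn-rr") {
      pt_hat[, active] <- ridge_predict_cols(
        K, pt$values[, active, drop = FALSE], train, test)
    } else {
      use_tp1 <- variant == "dyn-factor-tp1"
      blocks <- c(list(R = intersect(which(pt$meta$matrix == "R"), active)),
                  lapply(seq_len(r), function(k) {
                    intersect(which(pt$meta$matrix == "Phi" &
                                      pt$meta$col == k), active)
                  }))
      blocks <- Filter(length, blocks)
      for (b in seq_along(blocks)) {
        cols <- blocks[[b]]
        pt_hat[, cols] <- factor_block_predict(
          grm, pt$values[, cols, drop = FALSE], train, test,
          tp1_train = if (use_tp1) tp1 else NULL,
          tp1_test = if (use_tp1) tp1[test, , drop = FALSE] else NULL)
      }
    }
    audit_record(paste0("forecast-", variant, "-", mode), sp$it, sp$f,
                 variant, panel$line_ids[test], horizon)
    for (i in seq_along(test)) {
      g <- test[i]
      preds[[sp$it]][g, , horizon] <- assemble_and_propagate(
        pt_hat[i, ], r, p, mode,
        x_init = panel$values[g, , split_time],
        steps = length(horizon), elapsed = elapsed_fc,
        observed = if (mode == "iterative")
          panel$values[g, , split_time:(T_ - 1L)] else NULL)
    }
  }
  bk <- count_models(if (variant == "dyn-rr") "dyn-rr" else "dyn-factor",
                     p = p, T_ = T_, r = r)
  bk$split_time <- split_time
  bk$forecast_points <- length(horizon)
  new_prediction_set(paste0("forecast-", variant, "-", mode), preds,
                     horizon, plan, bk)
}

#' Scenario bookkeeping: model and column counts
#'
#' Pure arithmetic from the scenario configuration: how many models are
#' fit per cross-validation split, how many columns they predict, and how
#' many secondary columns they see.
#'
#' @param scenario one of `"st-stp"`, `"cv1"`, `"cv2.1"`, `"cv2.2"`,
#'   `"dyn-rr"`, `"dyn-factor"`.
#' @param p number of traits.
#' @param T_ number of time points.
#' @param r truncation rank (dynamicGP scenarios).
#' @return list with `models_per_split`, `prediction_columns`,
#'   `secondary_columns`, and for dynamicGP scenarios `r_entries`,
#'   `phi_modes`, `phi_mode_length`.
#' @export
count_models <- function(scenario, p, T_, r = NA) {
  switch(scenario,
    "st-stp" = list(models_per_split = p * T_, prediction_columns = p * T_,
                    secondary_columns = 0L),
    "cv1" = list(models_per_split = 1L, prediction_columns = p * T_,
                 secondary_columns = 0L),
    "cv2.1" = list(models_per_split = 1L,
                   prediction_columns = p * (T_ - 1L),
                   secondary_columns = p),
    "cv2.2" = list(models_per_split = T_ - 1L,
                   prediction_columns = p * (T_ - 1L),
                   secondary_columns = p),
    "dyn-rr" = list(models_per_split = r * p + r * r,
                    prediction_columns = r * p + r * r,
                    secondary_columns = 0L, r_entries = r * r,
                    phi_modes = r, phi_mode_length = p),
    "dyn-factor" = list(models_per_split = r + 1L,
                        prediction_columns = r * p + r * r,
                        secondary_columns = 0L, r_entries = r * r,
                        phi_modes = r, phi_mode_length = p),
    stopf("unknown scenario '%s'", scenario)
  )
}
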