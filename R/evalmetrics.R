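## Accuracy assessment.
##
## Snapshot accuracy: per trait-time cell, the Pearson correlation (and
## MSE) between true and predicted values across the test genotypes of a
## fold, averaged over folds and iterations. Longitudinal accuracy: per
## genotype-trait series and iteration, the correlation and MSE across the
## predicted time grid. Significance of a longitudinal correlation uses
## the threshold PCC = t_crit / sqrt(t_crit^2 + n - 2) at a Bonferroni-
## corrected alpha.

safe_pcc <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

#' Snapshot accuracy of a prediction set
#'
#' For every trait and predicted time point, the PCC and MSE across the
#' test genotypes of each fold, then averaged across folds and iterations
#' (equal weight per fold). Cells with zero variance in truth or
#' prediction yield an undefined PCC and are excluded from the mean (their
#' count is reported).
#'
#' @param pred a `prediction_set`.
#' @param truth the `phenotype_panel` holding the true values.
#' @return data.frame with columns `trait`, `time`, `pcc`, `mse`,
#'   `n_folds_used`, `n_undefined`.
#' @export
snapshot_accuracy <- function(pred, truth) {
  stopifnot(inherits(pred, "prediction_set"),
            inherits(truth, "phenotype_panel"))
  plan <- pred$plan
  d <- dim(truth$values)
  p <- d[2L]
  out <- expand.grid(trait = truth$trait_ids, time = pred$predicted_times,
                     stringsAsFactors = FALSE)
  acc_pcc <- acc_mse <- n_used <- n_undef <- matrix(
    0, p, length(pred$predicted_times))
  for (it in seq_along(pred$pred)) {
    arr <- pred$pred[[it]]
    folds <- if (is.null(plan)) {
      list(seq_len(d[1L]))
    } else {
      split(seq_len(d[1L]), plan$assignments[, it])
    }
    for (test in folds) {
      if (length(test) < 3L) next
      for (jt in seq_along(pred$predicted_times)) {
        t_ <- pred$predicted_times[jt]
        for (j in seq_len(p)) {
          yhat <- arr[test, j, t_]
          y <- truth$values[test, j, t_]
          if (anyNA(yhat)) next
          r <- safe_pcc(y, yhat)
          if (is.na(r)) {
            n_undef[j, jt] <- n_undef[j, jt] + 1L
          } else {
            acc_pcc[j, jt] <- acc_pcc[j, jt] + r
            acc_mse[j, jt] <- acc_mse[j, jt] + mean((y - yhat)^2)
            n_used[j, jt] <- n_used[j, jt] + 1L
          }
        }
      }
    }
  }
  out$pcc <- as.vector(acc_pcc / pmax(n_used, 1L))
  out$pcc[as.vector(n_used) == 0L] <- NA_real_
  out$mse <- as.vector(acc_mse / pmax(n_used, 1L))
  out$mse[as.vector(n_used) == 0L] <- NA_real_
  out$n_folds_used <- as.vector(n_used)
  out$n_undefined <- as.vector(n_undef)
  out
}

#' Longitudinal accuracy of a prediction set
#'
#' For every genotype, trait and iteration, the PCC and (untransformed)
#' MSE between predicted and true values across the predicted time grid.
#' Constant predicted series give an undefined PCC (recorded as `NA`,
#' never significant).
#'
#' @param pred a `prediction_set`.
#' @param truth the `phenotype_panel` holding the true values.
#' @param skip_initial drop the initial time point from the comparison
#'   when the scenario predicts it (for parity with scenarios seeded by
#'   it).
#' @return data.frame with columns `line`, `trait`, `iteration`, `pcc`,
#'   `mse`, `n_time`.
#' @export
longitudinal_accuracy <- function(pred, truth, skip_initial = TRUE) {
  stopifnot(inherits(pred, "prediction_set"),
            inherits(truth, "phenotype_panel"))
  times <- pred$predicted_times
  if (skip_initial) times <- setdiff(times, 1L)
  if (length(times) < 3L) stopf("need at least 3 predicted time points")
  d <- dim(truth$values)
  res <- vector("list", length(pred$pred))
  for (it in seq_along(pred$pred)) {
    arr <- pred$pred[[it]]
    pcc <- mse <- matrix(NA_real_, d[1L], d[2L])
    for (g in seq_len(d[1L])) {
      for (j in seq_len(d[2L])) {
        yhat <- arr[g, j, times]
        if (anyNA(yhat)) next
        y <- truth$values[g, j, times]
        pcc[g, j] <- safe_pcc(y, yhat)
        mse[g, j] <- mean((y - yhat)^2)
      }
    }
    keep <- !is.na(mse)
    res[[it]] <- data.frame(
      line = rep(truth$line_ids, d[2L])[keep],
      trait = rep(truth$trait_ids, each = d[1L])[keep],
      iteration = it,
      pcc = pcc[keep], mse = mse[keep], n_time = length(times)
    )
  }
  do.call(rbind, res)
}

#' Significance threshold for a Pearson correlation
#'
#' `t_crit / sqrt(t_crit^2 + n - 2)` with `t_crit` the two-sided critical
#' t value at the Bonferroni-corrected level `alpha / n_tests` on `n - 2`
#' degrees of freedom.
#'
#' @param n number of paired observations per correlation (>= 3).
#' @param alpha family-wise significance level.
#' @param n_tests Bonferroni family size.
#' @return the threshold PCC.
#' @export
pcc_significance_threshold <- function(n, alpha = 0.05, n_tests = 1L) {
  n <- check_count(n, "n", min = 3L)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  n_tests <- check_count(n_tests, "n_tests")
  t_crit <- stats::qt(1 - (alpha / n_tests) / 2, df = n - 2L)
  t_crit / sqrt(t_crit^2 + n - 2L)
}

#' Proportions of significant longitudinal correlations
#'
#' Per trait (and overall): the fraction of genotype-iteration series
#' whose PCC exceeds the threshold (positive) or falls below its negative
#' (negative). Undefined PCCs count in the denominator but never in a
#' numerator.
#'
#' @param long_table a [longitudinal_accuracy()] result.
#' @param threshold the [pcc_significance_threshold()] value.
#' @return list with `per_trait` (data.frame trait, n_series,
#'   prop_positive, prop_negative) and `overall_positive`,
#'   `overall_negative` (percentages across all series).
#' @export
significant_proportion <- function(long_table, threshold) {
  if (!nrow(long_table)) stopf("empty longitudinal table")
  sp <- split(long_table$pcc, long_table$trait)
  per_trait <- data.frame(
    trait = names(sp),
    n_series = vapply(sp, length, integer(1)),
    prop_positive = vapply(sp, function(x)
      mean(!is.na(x) & x > threshold), numeric(1)),
    prop_negative = vapply(sp, function(x)
      mean(!is.na(x) & x < -threshold), numeric(1)),
    row.names = NULL
  )
  list(per_trait = per_trait,
       overall_positive = 100 * mean(!is.na(long_table$pcc) &
                                       long_table$pcc > threshold),
       overall_negative = 100 * mean(!is.na(long_table$pcc) &
                                       long_table$pcc < -threshold),
       n_tests = nrow(long_table))
}
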