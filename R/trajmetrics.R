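## Roughness and convexity of developmental trajectories.
##
## Roughness: total variation, quadratic variation, coefficient of
## variation, RMS roughness and kurtosis of the detrended range-normalized
## series. Convexity: mean second difference, the leading coefficient of
## the least-squares parabola, and the mean chord deviation over all
## ordered index triples. Time is indexed 1..T with unit spacing in all
## regressions.

#' Range-normalize and linearly detrend a time series
#'
#' `y_norm = y / (max(y) - min(y))`, then ordinary least squares of
#' `y_norm` on the time index `1..T`, returning the residuals.
#'
#' @param y numeric series, length >= 3, `max(y) > min(y)`.
#' @return detrended normalized series (mean ~ 0, slope ~ 0).
#' @export
detrend_normalize <- function(y) {
  y <- as.numeric(y)
  T_ <- length(y)
  if (T_ < 3L) stopf("need at least 3 points")
  rng <- max(y) - min(y)
  if (rng <= 0) stopf("constant series cannot be normalized")
  yn <- y / rng
  x <- seq_len(T_)
  as.numeric(stats::lm.fit(cbind(1, x), yn)$residuals)
}

#' Roughness metrics of a trajectory
#'
#' `TV` and `QV` are the mean absolute and mean squared first difference
#' of the raw series; `CV` is `100 * sd(y) / mean(y)` of the raw series;
#' `Rq` is the root mean square of the detrended normalized series and
#' `Rku` its fourth-moment ratio (kurtosis), flagged `NA` when `Rq = 0`.
#'
#' @param y numeric series, length >= 3.
#' @return named list `TV`, `QV`, `CV`, `Rq`, `Rku`.
#' @export
roughness_metrics <- function(y) {
  y <- as.numeric(y)
  T_ <- length(y)
  if (T_ < 3L) stopf("need at least 3 points")
  dy <- diff(y)
  TV <- mean(abs(dy))
  QV <- mean(dy^2)
  m <- mean(y)
  if (abs(m) < 1e-300) stopf("mean(y) is zero; CV undefined")
  CV <- 100 * stats::sd(y) / m
  yd <- if (max(y) > min(y)) detrend_normalize(y) else rep(0, T_)
  Rq <- sqrt(mean(yd^2))
  Rku <- if (Rq > 0) mean(yd^4) / Rq^4 else NA_real_
  list(TV = TV, QV = QV, CV = CV, Rq = Rq, Rku = Rku)
}

#' Convexity metrics of a trajectory
#'
#' `MSD` is the mean second difference; `QC` the leading coefficient of
#' the least-squares parabola on the time index; `MCD` the mean, over all
#' ordered triples `i < j < k`, of the linear chord value at `j` minus
#' `y_j` (positive for convex, negative for concave shapes).
#'
#' @param y numeric series, length >= 3.
#' @return named list `MSD`, `QC`, `MCD`.
#' @export
convexity_metrics <- function(y) {
  y <- as.numeric(y)
  T_ <- length(y)
  if (T_ < 3L) stopf("need at least 3 points")
  MSD <- mean(diff(y, differences = 2L))
  x <- seq_len(T_)
  QC <- unname(stats::lm.fit(cbind(1, x, x^2), y)$coefficients[3L])
  # Exhaustive O(T^3) triple loop; T <= 25 keeps this at <= 2300 triples.
  s <- 0; cnt <- 0L
  for (i in seq_len(T_ - 2L)) {
    for (j in (i + 1L):(T_ - 1L)) {
      for (k in (j + 1L):T_) {
        chord <- ((k - j) * y[i] + (j - i) * y[k]) / (k - i)
        s <- s + (chord - y[j])
        cnt <- cnt + 1L
      }
    }
  }
  list(MSD = MSD, QC = QC, MCD = s / cnt)
}

#' Trajectory characteristics per trait, related to accuracy
#'
#' Computes the roughness and convexity metrics on each trait's mean
#' trajectory across genotypes (optionally per genotype) and, when a
#' per-trait accuracy summary is supplied, the Pearson correlation
#' between each metric and each accuracy column.
#'
#' @param panel a `phenotype_panel`.
#' @param accuracy optional data.frame with a `trait` column and numeric
#'   accuracy summaries (e.g. mean longitudinal PCC, significant
#'   proportion).
#' @param per_genotype compute metrics per genotype instead of on the mean
#'   trajectory.
#' @return list with `metrics` (one row per trait — or per genotype-trait —
#'   with TV, QV, CV, Rq, Rku, MSD, QC, MCD) and, when `accuracy` is
#'   given, `correlations` (metric x accuracy-column matrix; omitted with
#'   a warning for fewer than 3 traits).
#' @export
characterize_traits <- function(panel, accuracy = NULL,
                                per_genotype = FALSE) {
  stopifnot(inherits(panel, "phenotype_panel"))
  metric_row <- function(y) {
    unlist(c(roughness_metrics(y), convexity_metrics(y)))
  }
  if (per_genotype) {
    d <- dim(panel$values)
    rows <- expand.grid(line = panel$line_ids, trait = panel$trait_ids,
                        stringsAsFactors = FALSE)
    M <- t(mapply(function(g, j) metric_row(panel$values[g, j, ]),
                  match(rows$line, panel$line_ids),
                  match(rows$trait, panel$trait_ids)))
    metrics <- cbind(rows, as.data.frame(M))
  } else {
    M <- t(vapply(seq_along(panel$trait_ids), function(j) {
      metric_row(colMeans(panel$values[, j, ]))
    }, numeric(8L)))
    metrics <- data.frame(trait = panel$trait_ids, as.data.frame(M))
  }
  out <- list(metrics = metrics)
  if (!is.null(accuracy)) {
    if (nrow(metrics) < 3L || per_genotype) {
      warning("correlations omitted: need >= 3 traits on the mean trajectory")
      return(out)
    }
    acc <- accuracy[match(metrics$trait, accuracy$trait), , drop = FALSE]
    acc_cols <- names(acc)[vapply(acc, is.numeric, logical(1))]
    met_cols <- c("TV", "QV", "CV", "Rq", "Rku", "MSD", "QC", "MCD")
    cors <- sapply(acc_cols, function(a) {
      vapply(met_cols, function(m) {
        if (stats::sd(acc[[a]]) < 1e-12 || stats::sd(metrics[[m]]) < 1e-12) {
          NA_real_
        } else {
          stats::cor(metrics[[m]], acc[[a]])
        }
      }, numeric(1))
    })
    out$correlations <- as.matrix(cors)
  }
  out
}
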