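## Data containers and standard-format I/O: the phenotype panel (genotype x
## trait x time tensor), genotype matrices (CSV / VCF), the VanRaden genomic
## relationship matrix, min-max normalization, and Mantel-network trait
## pre-selection.

# Construct a phenotype_panel (internal).
new_phenotype_panel <- function(values, trait_ids, time_labels, gap_after,
                                gap_days, normalization = NULL) {
  structure(
    list(values = values, line_ids = dimnames(values)[[1L]],
         trait_ids = trait_ids, time_labels = time_labels,
         gap_after = as.integer(gap_after), gap_days = gap_days,
         normalization = normalization),
    class = "phenotype_panel"
  )
}

#' @export
print.phenotype_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("phenotype_panel: %d lines x %d traits x %d time points\n",
              d[1], d[2], d[3]))
  if (length(x$gap_after)) {
    cat(sprintf("  gaps after time indices: %s (%d day(s) each)\n",
                paste(x$gap_after, collapse = ", "), x$gap_days))
  }
  if (!is.null(x$normalization)) {
    cat(sprintf("  normalized: %s (per trait)\n", x$normalization$method))
  }
  invisible(x)
}

# Elapsed modeled days for each transition t -> t+1 (internal).
panel_elapsed <- function(panel) {
  T_ <- dim(panel$values)[3L]
  el <- rep(1L, T_ - 1L)
  el[panel$gap_after] <- 1L + panel$gap_days
  el
}

#' Write / read a phenotype panel as long-format CSV
#'
#' The file has exactly the columns `line_id,trait_id,time,value`, one row
#' per (line, trait, time point); `time` carries the day labels, from which
#' measurement gaps (elapsed > 1 day) are reconstructed on read.
#'
#' @param panel a `phenotype_panel`.
#' @param path file path.
#' @return `write_phenotypes` returns `path` invisibly; `read_phenotypes`
#'   returns a `phenotype_panel`.
#' @export
write_phenotypes <- function(panel, path) {
  stopifnot(inherits(panel, "phenotype_panel"))
  d <- dim(panel$values)
  df <- data.frame(
    line_id = rep(panel$line_ids, times = d[2] * d[3]),
    trait_id = rep(rep(panel$trait_ids, each = d[1]), times = d[3]),
    time = rep(panel$time_labels, each = d[1] * d[2]),
    value = as.vector(panel$values)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "trait_id", "time", "value")
  if (!identical(names(df)[seq_len(4)], need)) {
    stopf("phenotype CSV must have header %s", paste(need, collapse = ","))
  }
  key <- paste(df$line_id, df$trait_id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicate (line, trait, time) triple: (%s, %s, %s)",
          d$line_id, d$trait_id, d$time)
  }
  lines <- unique(df$line_id)
  traits <- unique(df$trait_id)
  times <- sort(unique(df$time))
  # Ragged grids: every line must cover the same (trait, time) grid.
  tab <- table(df$line_id)
  full <- length(traits) * length(times)
  if (any(tab != full) || nrow(df) != length(lines) * full) {
    grid <- expand.grid(line_id = lines, trait_id = traits, time = times,
                        stringsAsFactors = FALSE)
    gkey <- paste(grid$line_id, grid$trait_id, grid$time, sep = "\r")
    miss <- grid[!(gkey %in% key), , drop = FALSE]
    if (nrow(miss)) {
      m <- miss[1L, ]
      stopf("missing (line, trait, time) cell(s), e.g. (%s, %s, %s); %d total",
            m$line_id, m$trait_id, m$time, nrow(miss))
    }
    stopf("ragged time grid across lines")
  }
  arr <- array(NA_real_, c(length(lines), length(traits), length(times)),
               dimnames = list(lines, traits, NULL))
  arr[cbind(match(df$line_id, lines), match(df$trait_id, traits),
            match(df$time, times))] <- df$value
  dt <- diff(times)
  gap_after <- which(dt > min(dt))
  gap_days <- if (length(gap_after)) as.integer(max(dt) - min(dt)) else 0L
  new_phenotype_panel(arr, traits, times, gap_after, gap_days)
}

#' Read a genotype matrix from CSV or VCF
#'
#' CSV: lines in rows (first column = line id), markers in columns. VCF:
#' biallelic records are converted to alternate-allele dosages 0/1/2;
#' multi-allelic records are skipped with a message giving the count.
#'
#' @param path file path.
#' @param format `"csv"` or `"vcf"` (VCF import requires the vcfR package).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    dos <- as.matrix(df)
    if (!is.numeric(dos)) stopf("genotype CSV must be numeric dosages")
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stopf("VCF import requires the 'vcfR' package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi)) {
      message(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    dos <- t(apply(gt, 2L, count_alt))
    colnames(dos) <- rownames(gt)
  }
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    stopf("dosages must lie in [0, 2]")
  }
  line_ids <- rownames(dos)
  marker_ids <- colnames(dos)
  f <- colMeans(dos, na.rm = TRUE) / 2
  structure(
    list(dosages = dos, line_ids = line_ids, marker_ids = marker_ids,
         maf = pmin(f, 1 - f)),
    class = "genotype_matrix"
  )
}

#' Write a genotype matrix as CSV (lines in rows)
#' @param geno a `genotype_matrix`.
#' @param path file path.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  utils::write.csv(as.data.frame(geno$dosages), path, quote = FALSE)
  invisible(path)
}

#' Filter markers by minor allele frequency
#'
#' Retains exactly the markers with MAF at or above `threshold`.
#'
#' @param geno a `genotype_matrix`.
#' @param threshold MAF threshold in \[0, 0.5).
#' @return a `genotype_matrix` with the surviving markers.
#' @export
maf_filter <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (threshold < 0 || threshold >= 0.5) {
    stopf("threshold must lie in [0, 0.5)")
  }
  f <- colMeans(geno$dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= threshold
  geno$dosages <- geno$dosages[, keep, drop = FALSE]
  geno$marker_ids <- geno$marker_ids[keep]
  geno$maf <- maf[keep]
  geno
}

#' VanRaden genomic relationship matrix
#'
#' `G = W t(W) / (2 * sum(p_j (1 - p_j)))` with `W` the column-centered
#' dosage matrix and `p_j` the alternate-allele frequency (VanRaden method
#' 1). Missing dosages are mean-imputed per marker beforehand.
#'
#' @param geno a `genotype_matrix` with at least 2 polymorphic markers.
#' @return Object of class `grm`: list with `matrix` (symmetric PSD,
#'   line ids as dimnames) and `line_ids`.
#' @export
vanraden_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  D <- geno$dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2L]]
  }
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L) {
    stopf("need at least 2 polymorphic markers for a GRM")
  }
  W <- sweep(D[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- W %*% t(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(geno$line_ids, geno$line_ids)
  structure(list(matrix = G, line_ids = geno$line_ids), class = "grm")
}

# Apply per-trait normalization jointly across genotypes and time (internal).
normalize_panel <- function(panel, method) {
  v <- panel$values
  p <- dim(v)[2L]
  mins <- maxs <- numeric(p)
  for (j in seq_len(p)) {
    mins[j] <- min(v[, j, ])
    maxs[j] <- max(v[, j, ])
    rng <- maxs[j] - mins[j]
    if (rng <= 0) {
      stopf("trait '%s' is constant; cannot normalize", panel$trait_ids[j])
    }
    v[, j, ] <- if (method == "minmax") (v[, j, ] - mins[j]) / rng
                else v[, j, ] / rng
  }
  panel$values <- v
  panel$normalization <- list(method = method,
                              min = stats::setNames(mins, panel$trait_ids),
                              max = stats::setNames(maxs, panel$trait_ids))
  panel
}

#' Min-max normalize a phenotype panel
#'
#' Maps each trait to \[0, 1\] across all genotypes and time points jointly,
#' preserving trajectory shape within a trait; the per-trait min/max are
#' stored so [minmax_denormalize()] inverts the transform exactly.
#'
#' @param panel a `phenotype_panel` whose traits all have `max > min`.
#' @return the normalized panel with a `normalization` record.
#' @export
minmax_normalize <- function(panel) {
  stopifnot(inherits(panel, "phenotype_panel"))
  normalize_panel(panel, "minmax")
}

#' @rdname minmax_normalize
#' @export
minmax_denormalize <- function(panel) {
  stopifnot(inherits(panel, "phenotype_panel"))
  nz <- panel$normalization
  if (is.null(nz)) return(panel)
  v <- panel$values
  for (j in seq_along(panel$trait_ids)) {
    rng <- nz$max[j] - nz$min[j]
    v[, j, ] <- if (nz$method == "minmax") v[, j, ] * rng + nz$min[j]
                else v[, j, ] * rng
  }
  panel$values <- v
  panel$normalization <- NULL
  panel
}

#' Mantel-network trait pre-selection
#'
#' For every trait, the genotype-by-genotype Euclidean distance matrix of
#' its genotype x time profile is computed; the Mantel correlation of a
#' trait pair is the Pearson correlation of the lower triangles of their
#' distance matrices. Traits joined by Mantel correlation above
#' `corr_threshold` form a network whose communities (greedy modularity
#' maximization) define clusters; each cluster is represented by its trait
#' of highest mean heritability (ties broken by lexicographic trait id).
#'
#' @param panel a `phenotype_panel` with at least 3 genotypes.
#' @param h2_table trait x time matrix of heritabilities (rownames must
#'   cover the panel traits).
#' @param corr_threshold edge threshold in (0, 1), default 0.95.
#' @return Object of class `trait_clustering`: `mantel_corr`, `threshold`,
#'   `clusters` (named list of trait id vectors) and `representatives`.
#' @export
mantel_select_traits <- function(panel, h2_table, corr_threshold = 0.95) {
  stopifnot(inherits(panel, "phenotype_panel"))
  if (corr_threshold <= 0 || corr_threshold >= 1) {
    stopf("corr_threshold must lie strictly between 0 and 1")
  }
  n <- dim(panel$values)[1L]
  if (n < 3L) stopf("Mantel correlations need at least 3 genotypes")
  traits <- panel$trait_ids
  if (!all(traits %in% rownames(h2_table))) {
    stopf("h2_table must have a row for every panel trait")
  }
  dvec <- vapply(seq_along(traits), function(j) {
    as.vector(stats::dist(panel$values[, j, ]))
  }, numeric(n * (n - 1L) / 2L))
  M <- stats::cor(dvec)
  dimnames(M) <- list(traits, traits)
  adj <- (M > corr_threshold) & upper.tri(M)
  gr <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  comm <- igraph::cluster_fast_greedy(gr)
  memb <- igraph::membership(comm)
  clusters <- split(traits, memb)
  h2_mean <- rowMeans(h2_table[traits, , drop = FALSE])
  reps <- vapply(clusters, function(tr) {
    tr <- sort(tr)
    tr[which.max(h2_mean[tr])]
  }, character(1))
  names(clusters) <- names(reps) <- sprintf("cluster%02d",
                                            seq_along(clusters))
  structure(
    list(mantel_corr = M, threshold = corr_threshold, clusters = clusters,
         representatives = reps),
    class = "trait_clustering"
  )
}
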