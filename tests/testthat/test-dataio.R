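test_that("phenotype CSV round-trips and reports malformed grids", {
  g <- test_geno(4, 30)
  sim <- test_sim(g, p = 2, T_ = 8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(sim$panel, path)
  back <- read_phenotypes(path)
  expect_equal(back$values, sim$panel$values, tolerance = 1e-12)
  expect_equal(back$gap_after, sim$panel$gap_after)
  expect_equal(back$time_labels, sim$panel$time_labels)
  # drop one cell -> error naming the missing triple
  df <- read.csv(path)
  writeLines(c("line_id,trait_id,time,value",
               apply(df[-5, ], 1, paste, collapse = ",")), path)
  expect_error(read_phenotypes(path), "missing \\(line, trait, time\\)")
  # duplicate triple
  writeLines(c("line_id,trait_id,time,value",
               apply(df[c(1, seq_len(nrow(df))), ], 1, paste,
                     collapse = ",")), path)
  expect_error(read_phenotypes(path), "duplicate")
})

test_that("genotype CSV and VCF import produce dosage matrices", {
  g <- test_geno(5, 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, path)
  back <- read_genotypes(path, "csv")
  expect_equal(unname(back$dosages), unname(g$dosages))
  expect_equal(back$line_ids, g$line_ids)
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnp2\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",
    "1\t300\tsnp3\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1"
  ), vcf)
  expect_message(v <- read_genotypes(vcf, "vcf"), "1 multi-allelic")
  expect_equal(ncol(v$dosages), 2L)
  expect_equal(unname(v$dosages[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(v$dosages[, "snp3"]), c(2, 0, 1))
})

test_that("maf_filter retains exactly the markers at or above threshold", {
  g <- test_geno(10, 6)
  g$dosages[, 1] <- 0                      # MAF 0 -> dropped
  g$dosages[, 2] <- rep(c(0, 2), 5)        # MAF 0.5 -> kept
  g$dosages[, 3] <- c(2, rep(0, 9))        # MAF 0.1 -> kept at 0.05
  filt <- maf_filter(g, 0.05)
  expect_false("M00001" %in% filt$marker_ids)
  expect_true(all(c("M00002", "M00003") %in% filt$marker_ids))
  expect_true(min(filt$maf) >= 0.05)
  f <- colMeans(g$dosages) / 2
  n_below <- sum(pmin(f, 1 - f) < 0.05)
  expect_equal(ncol(filt$dosages), 6L - n_below)
  expect_error(maf_filter(g, 0.7), "threshold")
})

test_that("VanRaden GRM matches the brute-force definition", {
  g <- test_geno(50, 200, seed = 5)
  G <- vanraden_grm(g)
  # brute-force double loop
  D <- g$dosages
  p <- colMeans(D) / 2
  keep <- p > 0 & p < 1
  W <- sweep(D[, keep], 2, 2 * p[keep])
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  ref <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) ref[i, j] <- sum(W[i, ] * W[j, ]) / denom
  expect_lt(max(abs(G$matrix - ref)), 1e-10)
  expect_lt(max(abs(G$matrix - t(G$matrix))), 1e-10)
  expect_gte(min(eigen(G$matrix, only.values = TRUE)$values), -1e-8)
  # two identical lines: off-diagonal equals each diagonal
  g2 <- g
  g2$dosages[2, ] <- g2$dosages[1, ]
  G2 <- vanraden_grm(g2)$matrix
  expect_equal(G2[1, 2], G2[1, 1], tolerance = 1e-12)
  # adding a monomorphic marker leaves G unchanged
  g3 <- g
  g3$dosages <- cbind(g3$dosages, mono = 2)
  g3$marker_ids <- c(g3$marker_ids, "mono")
  expect_equal(vanraden_grm(g3)$matrix, G$matrix, tolerance = 1e-12)
  # all lines identical -> error
  g4 <- g
  g4$dosages <- matrix(rep(g4$dosages[1, ], each = 50), 50)
  expect_error(vanraden_grm(g4), "polymorphic")
})

test_that("min-max normalization maps per trait to [0,1] and inverts", {
  vals <- array(0, c(3, 2, 3), dimnames = list(paste0("L", 1:3),
                                               c("a", "b"), NULL))
  vals[, 1, ] <- matrix(c(2, 4, 6), 3, 3)
  vals[1, 1, ] <- c(2, 4, 6)
  vals[2, 1, ] <- c(2, 2, 2); vals[3, 1, ] <- c(6, 6, 6)
  vals[, 2, ] <- seq(0, 1, length.out = 9)
  pan <- longigp:::new_phenotype_panel(vals, c("a", "b"), 1:3,
                                       integer(0), 0L)
  nz <- minmax_normalize(pan)
  expect_equal(nz$values[1, 1, ], c(0, 0.5, 1))
  expect_equal(range(nz$values[, 2, ]), c(0, 1))
  back <- minmax_denormalize(nz)
  expect_equal(back$values, pan$values, tolerance = 1e-12)
  pan$values[, 2, ] <- 1
  expect_error(minmax_normalize(pan), "'b' is constant")
})

test_that("Mantel trait pre-selection clusters copies and keeps the best h2", {
  set.seed(8)
  n <- 20; T_ <- 6
  base <- matrix(rnorm(n * T_), n, T_)
  vals <- array(0, c(n, 3, T_),
                dimnames = list(sprintf("L%02d", 1:n), c("A", "B", "C"),
                                NULL))
  vals[, 1, ] <- base
  vals[, 2, ] <- 2 * base + 5       # affine copy of A
  vals[, 3, ] <- matrix(rnorm(n * T_), n, T_)
  pan <- longigp:::new_phenotype_panel(vals, c("A", "B", "C"), 1:T_,
                                       integer(0), 0L)
  h2 <- matrix(c(0.3, 0.6, 0.5), 3, T_,
               dimnames = list(c("A", "B", "C"), NULL))
  cl <- mantel_select_traits(pan, h2, 0.95)
  expect_equal(cl$mantel_corr["A", "B"], 1, tolerance = 1e-12)
  expect_lt(abs(cl$mantel_corr["A", "C"]), 0.5)
  expect_setequal(unname(cl$representatives), c("B", "C"))
  in_same <- any(vapply(cl$clusters, function(x)
    all(c("A", "B") %in% x), logical(1)))
  expect_true(in_same)
  # permutation invariance of the selected representatives
  pan2 <- pan
  pan2$values <- pan$values[, c(3, 1, 2), ]
  pan2$trait_ids <- c("C", "A", "B")
  cl2 <- mantel_select_traits(pan2, h2, 0.95)
  expect_setequal(unname(cl2$representatives),
                  unname(cl$representatives))
  # too few genotypes
  tiny <- pan
  tiny$values <- pan$values[1:2, , , drop = FALSE]
  tiny$line_ids <- pan$line_ids[1:2]
  expect_error(mantel_select_traits(tiny, h2), "3 genotypes")
})

test_that("Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 15
  m1 <- matrix(rnorm(n * 5), n)
  m2 <- m1 + matrix(rnorm(n * 5, sd = 0.5), n)
  vals <- array(0, c(n, 2, 5),
                dimnames = list(sprintf("L%02d", 1:n), c("A", "B"), NULL))
  vals[, 1, ] <- m1; vals[, 2, ] <- m2
  pan <- longigp:::new_phenotype_panel(vals, c("A", "B"), 1:5,
                                       integer(0), 0L)
  h2 <- matrix(0.5, 2, 5, dimnames = list(c("A", "B"), NULL))
  cl <- mantel_select_traits(pan, h2, 0.5)
  ref <- vegan::mantel(dist(m1), dist(m2), permutations = 0)$statistic
  expect_equal(cl$mantel_corr["A", "B"], unname(ref), tolerance = 1e-10)
})
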