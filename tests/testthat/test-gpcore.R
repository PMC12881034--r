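test_that("RR-BLUP recovers a single informative marker", {
  g <- test_geno(60, 30, seed = 12)
  # make all markers monomorphic except one
  g$dosages[, -7] <- 2
  y <- 0.5 * g$dosages[, 7] + 1
  m <- fit_rrblup(sub_geno(g, 1:45), y[1:45])
  pred <- predict_rrblup(m, sub_geno(g, 46:60))
  expect_gt(cor(pred, y[46:60]), 0.99)
})

test_that("ridge model predictions honor the dosage contract", {
  g <- test_geno(40, 60, seed = 13)
  at <- simulate_additive_traits(g, 1, h2 = 0.8, seed = 14)
  y <- at$values[, 1]
  m <- fit_rrblup(g, y)
  # identical test line -> its fitted value
  fitted <- predict_rrblup(m, g)
  expect_equal(predict_rrblup(m, sub_geno(g, 3)), fitted[3])
  # all-zero dosage line -> intercept
  z <- sub_geno(g, 1)
  z$dosages[] <- 0
  expect_equal(unname(predict_rrblup(m, z)), m$intercept)
  # permuted marker columns (with ids) -> identical predictions
  perm <- sample(ncol(g$dosages))
  gp <- g
  gp$dosages <- gp$dosages[, perm]
  gp$marker_ids <- gp$marker_ids[perm]
  expect_equal(predict_rrblup(m, gp), fitted)
  # marker mismatch errors
  gbad <- sub_geno(g, 1:5)
  gbad$dosages <- gbad$dosages[, -1, drop = FALSE]
  gbad$marker_ids <- gbad$marker_ids[-1]
  expect_error(predict_rrblup(m, gbad), "mismatch")
  # forced infinite shrinkage -> training mean
  mInf <- fit_rrblup(g, y, lambda = Inf)
  expect_equal(unname(predict_rrblup(mInf, sub_geno(g, 1:4))),
               rep(mean(y), 4))
  expect_error(fit_rrblup(g, rep(1, 40)), "variance")
})

test_that("null heritability yields predictive correlation centered at 0", {
  g <- test_geno(50, 80, seed = 15)
  cors <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    y <- rnorm(50)
    m <- fit_rrblup(sub_geno(g, 1:35), y[1:35])
    cor(predict_rrblup(m, sub_geno(g, 36:50)), y[36:50])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("RR-BLUP and GBLUP give equivalent predictions", {
  g <- test_geno(70, 150, seed = 16)
  at <- simulate_additive_traits(g, 1, h2 = 0.6, seed = 17)
  y <- at$values[, 1]
  tr <- 1:55; te <- 56:70
  m <- fit_rrblup(sub_geno(g, tr), y[tr])
  pr <- predict_rrblup(m, sub_geno(g, te))
  gb <- fit_gblup(vanraden_grm(g), y[tr], tr)
  expect_lt(max(abs(gb$predictions[te] - pr)), 1e-6)
  # identity GRM: no information sharing, test predictions = training mean
  id <- structure(list(matrix = diag(70), line_ids = g$line_ids),
                  class = "grm")
  dimnames(id$matrix) <- list(g$line_ids, g$line_ids)
  gb0 <- fit_gblup(id, y[tr], tr)
  expect_equal(unname(gb0$predictions[te]), rep(mean_gls <- gb0$mu, 15))
  # duplicated line in train and test: prediction tracks its training BLUP
  gdup <- g
  gdup$dosages[60, ] <- gdup$dosages[1, ]
  Gd <- vanraden_grm(gdup)
  gbd <- fit_gblup(Gd, y[tr], tr)
  expect_equal(unname(gbd$predictions[60]), unname(gbd$predictions[1]),
               tolerance = 1e-8)
})

test_that("choose_k follows the published rule", {
  expect_identical(choose_k(40, 10), 5L)
  expect_identical(choose_k(264, 1250), 66L)
  expect_identical(choose_k(4, 2), 1L)
})

test_that("the factor model reconstructs exact low-rank data", {
  set.seed(18)
  n <- 40; t_ <- 12; k <- 3
  F0 <- matrix(rnorm(n * k), n)
  L0 <- matrix(rnorm(k * t_), k)
  Y <- F0 %*% L0
  rownames(Y) <- sprintf("L%03d", 1:n)
  colnames(Y) <- sprintf("c%02d", 1:t_)
  id <- structure(list(matrix = diag(n), line_ids = rownames(Y)),
                  class = "grm")
  dimnames(id$matrix) <- list(rownames(Y), rownames(Y))
  fm <- fit_factor_mtgp(id, Y, k = 3)
  recon <- sweep(fm$F_train %*% fm$Lambda, 2, fm$beta, `+`)
  expect_lt(max(abs(recon - Y)), 1e-6)
  # reconstruction error never increases over iterations
  expect_true(all(diff(fm$recon_error) <= 1e-8))
  # identical columns -> one factor explains > 99% of the variance
  Y1 <- matrix(rep(rnorm(n), 8), n)
  rownames(Y1) <- rownames(Y); colnames(Y1) <- paste0("d", 1:8)
  fm1 <- fit_factor_mtgp(id, Y1, k = 2)
  sv <- svd(sweep(Y1, 2, colMeans(Y1)))$d
  expect_gt(sv[1]^2 / sum(sv^2), 0.99)
  expect_lt(tail(fm1$recon_error, 1), 1e-6)
  expect_error(fit_factor_mtgp(id, Y, k = n), "smaller")
})

test_that("factor model predictions are equivariant and GRM-aware", {
  g <- test_geno(60, 120, seed = 19)
  at <- simulate_additive_traits(g, 4, h2 = 0.7, seed = 20)
  G <- vanraden_grm(g)
  tr <- 1:45; te <- 46:60
  Y <- at$values
  fm <- fit_factor_mtgp(G, Y[tr, ], k = 2)
  p1 <- predict_factor_mtgp(fm, G, te)
  # column permutation -> permuted predictions
  perm <- c(3, 1, 4, 2)
  fmp <- fit_factor_mtgp(G, Y[tr, perm], k = 2)
  p2 <- predict_factor_mtgp(fmp, G, te)
  expect_equal(unname(p2), unname(p1[, perm]), tolerance = 1e-6)
  # identity GRM, no secondary -> column means
  id <- structure(list(matrix = diag(60), line_ids = g$line_ids),
                  class = "grm")
  dimnames(id$matrix) <- list(g$line_ids, g$line_ids)
  fm0 <- fit_factor_mtgp(id, Y[tr, ], k = 2)
  p0 <- predict_factor_mtgp(fm0, id, te)
  expect_equal(unname(p0),
               matrix(colMeans(Y[tr, ]), 15, 4, byrow = TRUE),
               tolerance = 1e-6)
  # secondary columns must be a strict, known subset
  expect_error(predict_factor_mtgp(fm, G, te,
                                   secondary_obs = list(cols = 1:4,
                                                        values = Y[te, ])),
               "strict")
  # near-degenerate CV2: observing all-but-one columns pulls the
  # predictions of the observed columns toward the observations
  sec <- 1:3
  pcv2 <- predict_factor_mtgp(fm, G, te,
                              secondary_obs = list(cols = sec,
                                                   values = Y[te, sec]))
  acc_cv1 <- mean(vapply(sec, function(j) cor(p1[, j], Y[te, j]),
                         numeric(1)))
  acc_cv2 <- mean(vapply(sec, function(j) cor(pcv2[, j], Y[te, j]),
                         numeric(1)))
  expect_gt(acc_cv2, acc_cv1)
})

test_that("secondary traits with high genetic correlation lift accuracy", {
  g <- test_geno(100, 250, seed = 21)
  G <- vanraden_grm(g)
  R <- diag(4)
  R[1, 3] <- R[3, 1] <- R[2, 4] <- R[4, 2] <- 0.9
  gains <- vapply(1:20, function(s) {
    at <- simulate_additive_traits(g, 4, h2 = 0.5, genetic_corr = R,
                                   seed = 300 + s)
    Y <- at$values
    tr <- 1:80; te <- 81:100
    fm <- fit_factor_mtgp(G, Y[tr, ], k = 2)
    cv1 <- predict_factor_mtgp(fm, G, te)
    cv2 <- predict_factor_mtgp(fm, G, te,
                               secondary_obs = list(cols = 3:4,
                                                    values = Y[te, 3:4]))
    mean(c(cor(cv2[, 1], Y[te, 1]), cor(cv2[, 2], Y[te, 2]))) -
      mean(c(cor(cv1[, 1], Y[te, 1]), cor(cv1[, 2], Y[te, 2])))
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("predictive ability rises with heritability", {
  g <- test_geno(80, 200, seed = 22)
  tr <- 1:60; te <- 61:80
  acc <- vapply(c(0.2, 0.5, 0.8), function(h2) {
    cors <- vapply(1:50, function(s) {
      at <- simulate_additive_traits(g, 1, h2 = h2, seed = 5000 + s)
      m <- fit_rrblup(sub_geno(g, tr), at$values[tr, 1])
      cor(predict_rrblup(m, sub_geno(g, te)), at$values[te, 1])
    }, numeric(1))
    mean(cors)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})
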