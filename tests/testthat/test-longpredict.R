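test_that("cross-validation plans partition lines with balanced folds", {
  ids <- sprintf("L%03d", 1:330)
  plan <- make_cv_plan(ids, n_folds = 5, n_iterations = 3, seed = 2)
  for (it in 1:3) {
    sizes <- table(plan$assignments[, it])
    expect_equal(unname(sizes), rep(66L, 5), ignore_attr = TRUE)
  }
  # every line is tested exactly once per iteration
  expect_true(all(rowSums(plan$assignments > 0) == 3))
  plan2 <- make_cv_plan(ids, 5, 3, seed = 2)
  expect_identical(plan$assignments, plan2$assignments)
  # uneven division: sizes differ by at most one
  plan3 <- make_cv_plan(ids[1:13], 4, 1, seed = 1)
  expect_lte(diff(range(table(plan3$assignments[, 1]))), 1)
  expect_error(make_cv_plan(ids[1:3], 5, 1), "exceeds")
})

test_that("pseudo-trait extraction pools r^2 + p*r aligned columns", {
  g <- test_geno(8, 40)
  sim <- test_sim(g, p = 50, T_ = 8, seed = 5)
  pt <- extract_pseudotraits(sim$panel, 2)
  expect_equal(ncol(pt$values), 104L)   # 4 + 100
  expect_equal(sum(pt$meta$matrix == "R"), 4L)
  expect_equal(sum(pt$meta$matrix == "Phi" & pt$meta$col == 1), 50L)
  # the sub-diagonal R entry is structurally zero across genotypes with
  # separated real eigenvalues -> flagged constant
  expect_true(pt$constant[["R.2.1"]])
  expect_true(all(abs(pt$values[, "R.2.1"]) < 1e-10))
  # deterministic under re-extraction
  pt2 <- extract_pseudotraits(sim$panel, 2)
  expect_identical(pt$values, pt2$values)
  # extracted eigenvalues match the generator's R diagonal
  sim2 <- test_sim(g, p = 6, T_ = 12, seed = 6, normalize = "none")
  pt3 <- extract_pseudotraits(sim2$panel, 2)
  for (gi in 1:8) {
    ev_true <- sort(diag(sim2$truth$R[, , gi]), decreasing = TRUE)
    ev_ext <- sort(diag(pt3$components[[gi]]$R), decreasing = TRUE)
    expect_equal(ev_ext, ev_true, tolerance = 1e-8)
  }
})

test_that("dynamicGP with oracle pseudo-traits reproduces the truth", {
  g <- test_geno(20, 60)
  sim <- test_sim(g, p = 5, T_ = 15, seed = 8, normalize = "range")
  plan <- make_cv_plan(g$line_ids, 4, 1, seed = 9)
  for (mode in c("recursive", "iterative")) {
    ps <- run_dynamicgp(sim$panel, plan = plan, r = 2, mode = mode,
                        oracle = TRUE)
    expect_lt(max(abs(ps$pred[[1]][, , 2:15] -
                        sim$panel$values[, , 2:15])), 1e-6)
    expect_equal(ps$predicted_times, 2:15)
    expect_true(all(is.na(ps$pred[[1]][, , 1])))
  }
})

test_that("dynamicGP cores fit the documented number of models", {
  g <- test_geno(30, 80)
  sim <- test_sim(g, p = 4, T_ = 10, seed = 10)
  grm <- vanraden_grm(g)
  plan <- make_cv_plan(g$line_ids, 3, 1, seed = 11)
  audit_start()
  ps <- run_dynamicgp(sim$panel, grm = grm, plan = plan, core = "factor",
                      r = 2, mode = "recursive")
  log <- audit_stop()
  # r + 1 = 3 factor models per split, 3 splits
  expect_equal(length(log), 3L * 3L)
  expect_true(all(grepl("^factor-", vapply(log, `[[`, "", "model_id"))))
  expect_equal(ps$bookkeeping$models_per_split, 3L)
  expect_equal(ps$bookkeeping$r_entries, 4L)
  expect_equal(ps$bookkeeping$phi_mode_length, 4L)
})

test_that("scenario bookkeeping reproduces the printed counts", {
  expect_equal(count_models("cv1", p = 50, T_ = 25)$prediction_columns,
               1250L)
  expect_equal(count_models("cv2.1", p = 50, T_ = 25)$prediction_columns,
               1200L)
  expect_equal(count_models("cv2.2", p = 50, T_ = 25)$models_per_split,
               24L)
  expect_equal(count_models("dyn-factor", p = 50, T_ = 25,
                            r = 2)$models_per_split, 3L)
  expect_equal(count_models("dyn-rr", p = 50, T_ = 25,
                            r = 2)$models_per_split, 104L)
  expect_equal(count_models("st-stp", p = 50, T_ = 25)$models_per_split,
               1250L)
})

test_that("CV2.1 with the secondary block withheld equals CV1", {
  g <- test_geno(24, 60)
  sim <- test_sim(g, p = 3, T_ = 8, h2 = 0.8, seed = 12)
  grm <- vanraden_grm(g)
  plan <- make_cv_plan(g$line_ids, 3, 1, seed = 13)
  a <- run_cv2_recursive(sim$panel, grm, plan, withhold_secondary = TRUE)
  b <- run_cv1_wide(sim$panel, grm = grm, plan = plan, core = "factor")
  expect_identical(a$pred[[1]][, , 2:8], b$pred[[1]][, , 2:8])
})

test_that("CV2.1 accuracy decays with temporal distance from t = 1", {
  g <- test_geno(60, 150, seed = 31)
  sim <- simulate_dynamic_phenome(g, p = 4, T_ = 12, r = 2, h2 = 0.9,
                                  seed = 14)
  grm <- vanraden_grm(g)
  plan <- make_cv_plan(g$line_ids, 4, 2, seed = 15)
  ps <- run_cv2_recursive(sim$panel, grm, plan)
  sa <- snapshot_accuracy(ps, sim$panel)
  by_t <- tapply(sa$pcc, sa$time, mean, na.rm = TRUE)
  expect_gt(by_t[["2"]], by_t[[as.character(12)]])
})

test_that("CV2.2 fits one model per transition and predicts 2..T", {
  g <- test_geno(24, 60)
  sim <- test_sim(g, p = 3, T_ = 6, h2 = 0.8, seed = 16)
  grm <- vanraden_grm(g)
  plan <- make_cv_plan(g$line_ids, 3, 1, seed = 17)
  audit_start()
  ps <- run_cv2_iterative(sim$panel, grm, plan)
  log <- audit_stop()
  expect_equal(length(log), 5L * 3L)   # (T-1) models x 3 splits
  expect_true(all(!is.na(ps$pred[[1]][, , 2:6])))
  expect_true(all(is.na(ps$pred[[1]][, , 1])))
  expect_equal(ps$bookkeeping$models_per_split, 5L)
})

test_that("forecasting predicts only beyond the split and rejects static", {
  g <- test_geno(25, 80)
  sim <- test_sim(g, p = 4, T_ = 15, seed = 18, normalize = "range")
  expect_error(run_forecast(sim$panel, split_time = 10, variant = "cv1"),
               "not applicable")
  ps <- run_forecast(sim$panel, split_time = 10, variant = "dyn-rr",
                     mode = "recursive", oracle = TRUE)
  expect_equal(ps$predicted_times, 11:15)
  expect_true(all(is.na(ps$pred[[1]][, , 1:10])))
  # noiseless oracle forecast matches the generated truth
  expect_lt(max(abs(ps$pred[[1]][, , 11:15] -
                      sim$panel$values[, , 11:15])), 1e-6)
  # iterative mode likewise
  psi <- run_forecast(sim$panel, split_time = 10, variant = "dyn-rr",
                      mode = "iterative", oracle = TRUE)
  expect_lt(max(abs(psi$pred[[1]][, , 11:15] -
                      sim$panel$values[, , 11:15])), 1e-6)
})

test_that("no scenario leaks test-line phenotypes at predicted times", {
  g <- test_geno(30, 80, seed = 51)
  sim <- simulate_dynamic_phenome(g, p = 3, T_ = 8, r = 2, h2 = 0.8,
                                  seed = 19)
  grm <- vanraden_grm(g)
  plan <- make_cv_plan(g$line_ids, 3, 1, seed = 20)
  audit_start()
  run_dynamicgp(sim$panel, geno = g, plan = plan, core = "rrblup",
                mode = "recursive")
  run_dynamicgp(sim$panel, grm = grm, plan = plan, core = "factor",
                mode = "recursive")
  run_dynamicgp(sim$panel, grm = grm, plan = plan, core = "factor",
                mode = "iterative", include_tp1 = TRUE)
  run_cv1_wide(sim$panel, grm = grm, plan = plan, core = "st-stp")
  run_cv1_wide(sim$panel, grm = grm, plan = plan, core = "factor")
  run_cv2_recursive(sim$panel, grm, plan)
  run_cv2_iterative(sim$panel, grm, plan)
  run_forecast(sim$panel, geno = g, split_time = 5, variant = "dyn-rr",
               mode = "recursive")
  log <- audit_stop()
  expect_gt(length(log), 0)
  viol <- audit_leakage(log)
  expect_equal(nrow(viol), 0L)
  # the documented allowances are actually exercised (t=1 and preceding-
  # time secondary cells for test lines are on record)
  entered <- do.call(rbind, lapply(log, `[[`, "entered_test_cells"))
  expect_gt(nrow(entered), 0)
  expect_true(all(entered$time >= 1))
})
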