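#!/usr/bin/env Rscript
# Step 4 — run the prediction scenarios under cross-validation.
#
# Compares, over a shared 5-fold cross-validation plan, the dynamics-based
# configurations (dynamicGP with ridge or latent-factor core, iterative
# and recursive, with and without the initial state as secondary traits)
# against the direct configurations (single-trait models per trait-time
# pair, one latent-factor model over all 1250 columns, and the CV2
# variants conditioning on the initial or preceding time point). Two
# iterations of 5-fold CV keep the run desk-sized; pass a first argument
# to change the iteration count. Predictions are written as long CSVs
# under results/predictions/.

suppressMessages(library(longigp))

args <- commandArgs(trailingOnly = TRUE)
n_iter <- if (length(args)) as.integer(args[[1]]) else 2L

pan <- read_phenotypes(file.path("results", "data", "phenotypes.csv"))
geno <- read_genotypes(file.path("results", "data", "genotypes.csv"))
grm <- vanraden_grm(geno)
plan <- make_cv_plan(geno$line_ids, n_folds = 5, n_iterations = n_iter,
                     seed = 11L)
out <- file.path("results", "predictions")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_predset <- function(ps, file) {
  d <- dim(pan$values)
  rows <- lapply(seq_along(ps$pred), function(it) {
    arr <- ps$pred[[it]][, , ps$predicted_times, drop = FALSE]
    data.frame(
      line_id = rep(pan$line_ids, times = d[2] * length(ps$predicted_times)),
      trait_id = rep(rep(pan$trait_ids, each = d[1]),
                     times = length(ps$predicted_times)),
      time = rep(pan$time_labels[ps$predicted_times], each = d[1] * d[2]),
      predicted = as.vector(arr),
      iteration = it,
      fold = rep(plan$assignments[, it],
                 times = d[2] * length(ps$predicted_times))
    )
  })
  write.csv(do.call(rbind, rows), file.path(out, file), row.names = FALSE,
            quote = FALSE)
}

scenarios <- list(
  list(file = "st_stp.csv",
       run = function() run_cv1_wide(pan, grm = grm, plan = plan,
                                     core = "st-stp")),
  list(file = "cv1_factor.csv",
       run = function() run_cv1_wide(pan, grm = grm, plan = plan,
                                     core = "factor")),
  list(file = "cv2_1.csv",
       run = function() run_cv2_recursive(pan, grm, plan)),
  list(file = "cv2_2.csv",
       run = function() run_cv2_iterative(pan, grm, plan)),
  list(file = "dyngp_rr_recursive.csv",
       run = function() run_dynamicgp(pan, geno = geno, plan = plan,
                                      core = "rrblup", r = 2,
                                      mode = "recursive")),
  list(file = "dyngp_rr_iterative.csv",
       run = function() run_dynamicgp(pan, geno = geno, plan = plan,
                                      core = "rrblup", r = 2,
                                      mode = "iterative")),
  list(file = "dyngp_factor_tp1_recursive.csv",
       run = function() run_dynamicgp(pan, grm = grm, plan = plan,
                                      core = "factor", r = 2,
                                      mode = "recursive",
                                      include_tp1 = TRUE)),
  list(file = "dyngp_factor_tp1_iterative.csv",
       run = function() run_dynamicgp(pan, grm = grm, plan = plan,
                                      core = "factor", r = 2,
                                      mode = "iterative",
                                      include_tp1 = TRUE))
)

for (sc in scenarios) {
  t0 <- proc.time()[3]
  ps <- sc$run()
  write_predset(ps, sc$file)
  message(sprintf("%-32s %s  (%d model(s)/split, %.1f s)",
                  ps$scenario, sc$file,
                  ps$bookkeeping$models_per_split, proc.time()[3] - t0))
}
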