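#!/usr/bin/env Rscript
# Step 5 — snapshot and longitudinal accuracy with significance.
#
# For every scenario run in step 4: the Pearson correlation and MSE
# between predicted and true values (i) across genotypes per trait-time
# cell, averaged over folds ("snapshot"), and (ii) across time per
# genotype-trait series ("longitudinal"). Longitudinal correlations are
# tested against the Bonferroni-corrected threshold over the family of
# all evaluated series. Writes snapshot.csv, longitudinal.csv,
# significance.csv and summary.json under results/evaluation/.

suppressMessages(library(longigp))

pan <- read_phenotypes(file.path("results", "data", "phenotypes.csv"))
pred_dir <- file.path("results", "predictions")
out <- file.path("results", "evaluation")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_predset <- function(file) {
  df <- read.csv(file.path(pred_dir, file))
  iters <- sort(unique(df$iteration))
  times_idx <- match(sort(unique(df$time)), pan$time_labels)
  d <- dim(pan$values)
  plan <- structure(
    list(line_ids = pan$line_ids,
         n_folds = max(df$fold), n_iterations = length(iters),
         assignments = do.call(cbind, lapply(iters, function(it) {
           sub <- df[df$iteration == it, c("line_id", "fold")]
           sub <- sub[!duplicated(sub$line_id), ]
           sub$fold[match(pan$line_ids, sub$line_id)]
         }))),
    class = "cv_plan"
  )
  pred <- lapply(iters, function(it) {
    arr <- array(NA_real_, d, dimnames = dimnames(pan$values))
    sub <- df[df$iteration == it, ]
    arr[cbind(match(sub$line_id, pan$line_ids),
              match(sub$trait_id, pan$trait_ids),
              match(sub$time, pan$time_labels))] <- sub$predicted
    arr
  })
  longigp:::new_prediction_set(sub("\\.csv$", "", file), pred, times_idx,
                               plan, list())
}

files <- list.files(pred_dir, pattern = "\\.csv$")
snapshot_all <- longitudinal_all <- signif_all <- list()
summary <- list()
for (f in files) {
  ps <- read_predset(f)
  sa <- snapshot_accuracy(ps, pan)
  la <- longitudinal_accuracy(ps, pan, skip_initial = TRUE)
  th <- pcc_significance_threshold(n = la$n_time[1], alpha = 0.05,
                                   n_tests = nrow(la))
  sp <- significant_proportion(la, th)
  sc <- ps$scenario
  snapshot_all[[sc]] <- cbind(scenario = sc, sa)
  longitudinal_all[[sc]] <- cbind(scenario = sc, la)
  signif_all[[sc]] <- cbind(scenario = sc, sp$per_trait)
  summary[[sc]] <- list(
    mean_snapshot_pcc = mean(sa$pcc, na.rm = TRUE),
    mean_snapshot_mse = mean(sa$mse, na.rm = TRUE),
    mean_longitudinal_pcc = mean(la$pcc, na.rm = TRUE),
    mean_longitudinal_mse = mean(la$mse, na.rm = TRUE),
    pcc_threshold = th,
    pct_significant_positive = sp$overall_positive,
    pct_significant_negative = sp$overall_negative,
    n_series = sp$n_tests
  )
  message(sprintf(
    "%-32s snapshot PCC %.3f | longitudinal PCC %.3f | %5.1f%% significant+",
    sc, summary[[sc]]$mean_snapshot_pcc,
    summary[[sc]]$mean_longitudinal_pcc, sp$overall_positive))
}
write.csv(do.call(rbind, snapshot_all), file.path(out, "snapshot.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(do.call(rbind, longitudinal_all),
          file.path(out, "longitudinal.csv"), row.names = FALSE,
          quote = FALSE)
write.csv(do.call(rbind, signif_all), file.path(out, "significance.csv"),
          row.names = FALSE, quote = FALSE)
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
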