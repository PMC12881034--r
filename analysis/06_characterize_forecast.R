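#!/usr/bin/env Rscript
# Step 6 — trajectory characteristics and CV3 forecasting.
#
# (a) Roughness (TV, QV, CV, Rq, Rku) and convexity (MSD, QC, MCD) of each
# trait's mean developmental trajectory, correlated with that trait's
# mean longitudinal accuracy and significant proportion per scenario.
# (b) CV3 forecasting: dynamicGP variants trained on time points 1-20
# predict time points 21-25 from the observed state at t = 20; the static
# configurations cannot forecast by construction.

suppressMessages(library(longigp))

pan <- read_phenotypes(file.path("results", "data", "phenotypes.csv"))
out <- "results"

## (a) trajectory characteristics vs accuracy
long_path <- file.path(out, "evaluation", "longitudinal.csv")
sig_path <- file.path(out, "evaluation", "significance.csv")
ch0 <- characterize_traits(pan)
write.csv(ch0$metrics, file.path(out, "characteristics.csv"),
          row.names = FALSE, quote = FALSE)
if (file.exists(long_path)) {
  la <- read.csv(long_path)
  sg <- read.csv(sig_path)
  cors <- list()
  for (sc in unique(la$scenario)) {
    sub <- la[la$scenario == sc, ]
    acc <- aggregate(pcc ~ trait, sub, mean, na.action = na.omit)
    names(acc)[2] <- "mean_longitudinal_pcc"
    acc$prop_significant <- sg$prop_positive[sg$scenario == sc][
      match(acc$trait, sg$trait[sg$scenario == sc])]
    ch <- characterize_traits(pan, accuracy = acc)
    cors[[sc]] <- data.frame(scenario = sc,
                             metric = rownames(ch$correlations),
                             ch$correlations, row.names = NULL)
    message(sprintf("%-32s cor(Rq, longitudinal PCC) = %+.2f", sc,
                    ch$correlations["Rq", "mean_longitudinal_pcc"]))
  }
  write.csv(do.call(rbind, cors),
            file.path(out, "metric_accuracy_correlations.csv"),
            row.names = FALSE, quote = FALSE)
} else {
  message("run analysis/05_evaluate.R first for the correlation block")
}

## (b) forecasting the last 5 time points
geno <- read_genotypes(file.path("results", "data", "genotypes.csv"))
grm <- vanraden_grm(geno)
fc <- list()
for (variant in c("dyn-rr", "dyn-factor", "dyn-factor-tp1")) {
  for (mode in c("recursive", "iterative")) {
    ps <- run_forecast(pan, geno = geno, grm = grm, split_time = 20,
                       variant = variant, mode = mode)
    sa <- snapshot_accuracy(ps, pan)
    la <- longitudinal_accuracy(ps, pan, skip_initial = FALSE)
    fc[[paste(variant, mode)]] <- data.frame(
      variant = variant, mode = mode,
      mean_snapshot_pcc = mean(sa$pcc, na.rm = TRUE),
      mean_longitudinal_pcc = mean(la$pcc, na.rm = TRUE),
      mean_mse = mean(sa$mse, na.rm = TRUE))
    message(sprintf(
      "forecast %-15s %-9s snapshot PCC %.3f | longitudinal PCC %.3f",
      variant, mode, mean(sa$pcc, na.rm = TRUE),
      mean(la$pcc, na.rm = TRUE)))
  }
}
write.csv(do.call(rbind, fc), file.path(out, "forecast_summary.csv"),
          row.names = FALSE, quote = FALSE)
res <- tryCatch(run_forecast(pan, split_time = 20, variant = "cv1"),
                error = function(e) conditionMessage(e))
message("static scenario in forecast mode: ", res)
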