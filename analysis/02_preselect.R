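#!/usr/bin/env Rscript
# Step 2 — Mantel-network trait pre-selection.
#
# High-throughput phenotyping pipelines derive hundreds of near-duplicate
# traits; representative traits are chosen by clustering the network of
# pairwise Mantel correlations (between the genotype x time matrices of
# each trait pair) and keeping the trait with the highest mean
# heritability per cluster. To demonstrate the step on data with known
# redundancy, the simulated panel is augmented with affine copies of ten
# of its traits (plus measurement noise); the selection should place each
# copy with its source and keep one representative per group.

suppressMessages(library(longigp))

pan <- read_phenotypes(file.path("results", "data", "phenotypes.csv"))
set.seed(1)
d <- dim(pan$values)
copies <- sprintf("T%02d", 1:10)
aug <- array(0, c(d[1], d[2] + 10, d[3]),
             dimnames = list(pan$line_ids,
                             c(pan$trait_ids, paste0(copies, "copy")),
                             NULL))
aug[, seq_len(d[2]), ] <- pan$values
for (i in seq_along(copies)) {
  src <- match(copies[i], pan$trait_ids)
  aug[, d[2] + i, ] <- 0.8 * pan$values[, src, ] + 0.1 +
    rnorm(d[1] * d[3], sd = 1e-4)
}
pan2 <- longigp:::new_phenotype_panel(aug, dimnames(aug)[[2]],
                                      pan$time_labels, pan$gap_after,
                                      pan$gap_days)
# Flat heritability table except the copies, which get a higher mean so
# the tie-break is exercised deterministically.
h2 <- matrix(0.5, d[2] + 10, d[3], dimnames = list(pan2$trait_ids, NULL))
h2[paste0(copies, "copy"), ] <- 0.6

cl <- mantel_select_traits(pan2, h2, corr_threshold = 0.95)
sizes <- vapply(cl$clusters, length, integer(1))
message(sprintf("%d clusters from %d traits; %d clusters have > 1 member",
                length(cl$clusters), d[2] + 10, sum(sizes > 1)))
recovered <- sum(vapply(seq_along(copies), function(i) {
  any(vapply(cl$clusters, function(tr)
    all(c(copies[i], paste0(copies[i], "copy")) %in% tr), logical(1)))
}, logical(1)))
message(sprintf("copies clustered with their source: %d / 10", recovered))

out <- file.path("results")
dir.create(out, showWarnings = FALSE)
memb <- data.frame(
  trait = unlist(cl$clusters, use.names = FALSE),
  cluster = rep(names(cl$clusters), sizes),
  representative = rep(unname(cl$representatives), sizes)
)
write.csv(memb, file.path(out, "trait_clusters.csv"), row.names = FALSE,
          quote = FALSE)
message(sprintf("representatives retained: %d (written to %s)",
                length(cl$representatives),
                file.path(out, "trait_clusters.csv")))
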