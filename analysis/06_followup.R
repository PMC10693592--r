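#!/usr/bin/env Rscript
# Stage 6 — pattern analysis after the ML stage and synthetic validation
# experiments: PR-vs-Others split, tail communities, strain frequencies,
# and Bonferroni-corrected pairwise contrasts with significance letters.

library(syncomscreen)
dir.create("results", showWarnings = FALSE)
seed <- 20240915
cfg <- generator_config()

scr <- generate_screen(cfg, seed = seed)
train <- preprocess_screen(scr$train, center = "mean")
agg <- aggregate_by_box(train)
agg <- agg[!(agg$treatment %in% train$controls), ]

sp <- split_pr_vs_others(
  scr$communities[scr$communities$community_id %in% agg$community_id, ],
  pr_strains(cfg), agg)
cat(sprintf("PR Strains group: n=%d, median %.2f log10 CFU/g; Others: n=%d, median %.2f\n",
            sp$n_pr, sp$median_pr, sp$n_others, sp$median_others))
write.csv(sp$groups, "results/groups.csv", row.names = FALSE)

thr <- screen_thresholds(train)
boundary <- mean(thr$threshold, na.rm = TRUE)
tail_ids <- tail_communities(sp, agg, boundary)
cat(sprintf("Tail of the Others group (< %.2f): %d communities\n",
            boundary, length(tail_ids)))
freq <- strain_frequency_in(scr$communities, ids = tail_ids)
freq <- freq[order(-freq$count), ]
write.csv(freq, "results/tail_strain_frequency.csv", row.names = FALSE)
if (length(tail_ids)) {
  cat("Most frequent strains in the tail:\n")
  print(head(freq, 4))
}

# synthetic validation experiment: focal strains singly and in combination
treatments <- list(
  axenic = character(),
  pr1 = "strain_01", pr2 = "strain_02", pr3 = "strain_03",
  intermediate = "strain_04",
  pr1_pr2 = c("strain_01", "strain_02"),
  int_weak = c("strain_04", "strain_05"))
v <- generate_validation_experiment(cfg, treatments, 6, seed = seed + 1)
lg <- log10_transform(partition_ambiguous(v$data))
res <- validation_contrasts(lg)
ct <- res$contrasts
ct$letters_a <- res$letters[ct$a]
ct$letters_b <- res$letters[ct$b]
write.csv(ct, "results/validation_contrasts.csv", row.names = FALSE)
cat(sprintf("Best model: %s; %d pairwise contrasts (Bonferroni family)\n",
            res$best_model, res$family_size))
cat("Significance letters:\n")
print(res$letters)
ax <- ct[ct$a == "axenic" | ct$b == "axenic", ]
cat("Estimated reductions vs axenic (log10):\n")
for (i in seq_len(nrow(ax))) {
  other <- if (ax$a[i] == "axenic") ax$b[i] else ax$a[i]
  est <- if (ax$a[i] == "axenic") -ax$estimate[i] else ax$estimate[i]
  cat(sprintf("  %-12s %6.2f  (adj. p %.3g)\n", other, est, ax$p_bonferroni[i]))
}
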