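#!/usr/bin/env Rscript
# Stage 1 — design arithmetic and synthetic screen generation.
#
# Computes the expected-prevalence curve that motivates the 35-strain pool /
# 5-strain community / 136-box design, generates the default synthetic
# training and test screens, and writes the design tables.

library(syncomscreen)
dir.create("results", showWarnings = FALSE)
seed <- 20240915

curve <- prevalence_curve(k = 5, N = 136, n_range = 10:60)
write.csv(curve, "results/prevalence_curve.csv", row.names = FALSE)
cat(sprintf("Expected prevalence at k=5, n=35, N=136: %.2f communities/strain\n",
            expected_prevalence(design_spec(5, 35, 136))))

cfg <- generator_config()
scr <- generate_screen(cfg, seed = seed)

write_communities(scr$communities, "results/communities.csv")
ape::write.tree(scr$tree, "results/strain_tree.nwk")

pl <- scr$train$plants
screen_pl <- pl[!(pl$treatment %in% scr$train$controls), ]
rp <- realized_prevalence(
  scr$communities[scr$communities$community_id %in% screen_pl$community_id, ],
  default_pool(cfg$pool_size))
write.csv(rp, "results/realized_prevalence.csv", row.names = FALSE)

cat(sprintf("Training screen: %d communities, %d plants over %d experiments\n",
            length(unique(screen_pl$community_id)), nrow(screen_pl),
            length(unique(screen_pl$experiment))))
te <- scr$test$plants
test_comms <- unique(te$community_id[!(te$treatment %in% scr$test$controls)])
cat(sprintf("Test screen: %d communities (incl. SynCom-Low/High)\n",
            length(test_comms)))
cat(sprintf("Realized prevalence: %d-%d communities per strain (expected %.1f)\n",
            min(rp$prevalence), max(rp$prevalence), 5 / 35 * 136))
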