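test_that("generator configuration validates its fields", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(box_sd = -1), "standard deviations")
  expect_error(generator_config(ambiguity_rate = 1.4), "ambiguity_rate")
  expect_error(generator_config(nonsense = 1), "unknown generator fields")
  expect_error(generator_config(community_size = 50L), "exceed")
  expect_equal(pr_strains(generator_config()),
               c("strain_01", "strain_02", "strain_03"))
})

test_that("screens reproduce bit-for-bit under the same seed", {
  a <- generate_screen(generator_config(), seed = 41)
  b <- generate_screen(generator_config(), seed = 41)
  expect_identical(a$train$plants, b$train$plants)
  expect_identical(a$train$strains, b$train$strains)
  expect_identical(a$test$plants, b$test$plants)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c_ <- generate_screen(generator_config(), seed = 42)
  expect_false(identical(a$train$plants$pathogen_cfu,
                         c_$train$plants$pathogen_cfu))
})

test_that("the default screen has the study's dimensions", {
  scr <- generate_screen(generator_config(), seed = 43)
  pl <- scr$train$plants
  screen_pl <- pl[!(pl$treatment %in% scr$train$controls), ]
  expect_equal(length(unique(screen_pl$community_id)), 136)
  expect_equal(nrow(screen_pl), 544)
  expect_equal(sort(unique(pl$experiment)), c("exp1", "exp2"))
  # one box per community, nested in experiment
  expect_equal(anyDuplicated(unique(screen_pl[, c("community_id", "box_id")])$community_id), 0)
  te <- scr$test$plants
  test_comms <- unique(te$community_id[!(te$treatment %in% scr$test$controls)])
  expect_equal(length(test_comms), 70)
  expect_true(all(c("SynCom-Low", "SynCom-High") %in% test_comms))
  # test compositions disjoint from training compositions
  memb <- split(scr$communities$strain_id, scr$communities$community_id)
  train_comms <- unique(screen_pl$community_id)
  key <- function(ids) vapply(memb[ids], paste, character(1), collapse = "|")
  expect_length(intersect(key(train_comms), key(test_comms)), 0)
})

test_that("the null generator produces pure noise around the axenic mean", {
  cfg <- small_null_config()
  cfg$box_sd <- 0
  cfg <- syncomscreen:::validate_generator_config(unclass(cfg))
  scr <- generate_screen(cfg, seed = 44)
  y <- log10(scr$train$plants$pathogen_cfu)
  y <- y[!is.na(y)]
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - (8.5 + scr$truth$experiment_effects["exp1"])), 3 * se)
})

test_that("ground truth reproduces the generator's expected values", {
  scr <- generate_screen(generator_config(), seed = 45)
  cfg <- scr$truth$config
  tb <- scr$truth$boxes
  memb <- split(scr$communities$strain_id, scr$communities$community_id)
  for (i in sample(nrow(tb), 25)) {
    cid <- tb$community_id[i]
    if (is.na(cid)) {
      expect_equal(tb$expected_log10[i],
                   cfg$axenic_mean + tb$exp_effect[i])
    } else {
      fe <- syncomscreen:::community_fixed_effect(memb[[cid]], cfg)
      expect_equal(tb$expected_log10[i],
                   cfg$axenic_mean + tb$exp_effect[i] + unname(fe["total"]))
    }
  }
  # per-plant records rebuild the observed values exactly
  tp <- scr$truth$plants
  tp <- tp[!is.na(tp$pathogen_log10), ]
  j <- merge(tp, tb, by = "box_id")
  rebuilt <- j$expected_log10 + j$commensal_term + j$evenness_term +
    j$u_box + j$residual
  expect_equal(rebuilt, j$pathogen_log10, tolerance = 1e-12)
})

test_that("strong-strain coverage matches the hypergeometric closed form", {
  cfg <- generator_config()
  p_expected <- 1 - choose(32, 5) / choose(35, 5)
  cs <- assemble_communities(default_pool(35), design_spec(5, 35, 4000),
                             seed = 46, enforce_unique = FALSE)
  has_pr <- vapply(cs$communities,
                   function(m) any(pr_strains(cfg) %in% m), logical(1))
  se <- sqrt(p_expected * (1 - p_expected) / 4000)
  expect_lt(abs(mean(has_pr) - p_expected), 3.5 * se)
})

test_that("validation experiments recover the implanted effect sizes", {
  cfg <- generator_config()
  treatments <- list(
    axenic = character(), pr_single = "strain_01",
    pr_pair = c("strain_01", "strain_02"), intermediate = "strain_04",
    int_weak = c("strain_04", "strain_05"))
  diffs <- sapply(1:6, function(s) {
    v <- generate_validation_experiment(cfg, treatments,
                                        n_boxes_per_treatment = 6,
                                        seed = 600 + s)
    lg <- log10_transform(partition_ambiguous(v$data))
    med <- tapply(lg$plants$pathogen_cfu, lg$plants$treatment, median)
    med[c("pr_single", "pr_pair", "intermediate", "int_weak")] - med["axenic"]
  })
  avg <- rowMeans(diffs)
  expect_lt(abs(avg["pr_single"] - (-2)), 0.3)
  expect_lt(abs(avg["pr_pair"] - (-4)), 0.45) # saturation softens the pair
  expect_lt(abs(avg["intermediate"] - (-1)), 0.3)
  # the designated synergy improves on the intermediate strain alone
  expect_lt(avg["int_weak"] - avg["intermediate"], -0.8)
  # 6 boxes x 4 plants = 24 records per treatment
  v <- generate_validation_experiment(cfg, treatments, 6, seed = 601)
  expect_true(all(table(v$data$plants$treatment) == 24))
  expect_error(generate_validation_experiment(cfg, list(x = "strain_99"), 2, 1),
               "unknown strain")
})

test_that("simulated trees cover the pool with positive branch lengths", {
  pool <- default_pool(20)
  tr <- simulate_tree(pool, seed = 47)
  expect_setequal(tr$tip.label, pool$strain_ids)
  expect_true(all(tr$edge.length > 0))
  d <- stats::cophenetic(tr)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_identical(ape::write.tree(simulate_tree(pool, 47)),
                   ape::write.tree(tr))
})

test_that("detection floors and ambiguity flags behave as configured", {
  scr <- generate_screen(generator_config(), seed = 48)
  st <- scr$train$strains
  floored <- st$cfu_per_g[st$flag == "below_detection"]
  expect_true(all(floored == 10^3.5))
  expect_true(all(st$cfu_per_g >= 10^3.5))
  # ambiguity rides on the designated pairs only
  amb <- st[st$flag == "ambiguous", ]
  expect_gt(nrow(amb), 0)
  cfg <- generator_config()
  pair_pool <- c(cfg$ambiguous_pairs$strain_a, cfg$ambiguous_pairs$strain_b)
  expect_true(all(amb$strain_id %in% pair_pool))
  # groups always have exactly two members with a shared pooled value
  sizes <- table(amb$ambiguity_group)
  expect_true(all(sizes == 2))
  vals <- tapply(amb$cfu_per_g, amb$ambiguity_group,
                 function(v) length(unique(v)))
  expect_true(all(vals == 1))
})
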