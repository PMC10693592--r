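test_that("the designated-strain split is an exhaustive disjoint partition", {
  comms <- list(c1 = c("A", "B", "C", "D", "E"), c2 = c("B", "C", "D", "E", "F"),
                c3 = c("A", "F", "G", "H", "I"))
  bm <- tibble::tibble(community_id = c("c1", "c2", "c3"),
                       median_pathogen = c(5, 8, 5.5))
  sp <- split_pr_vs_others(comms, "A", bm)
  expect_equal(sp$groups$group, c("PR Strains", "Others", "PR Strains"))
  expect_equal(sp$n_pr + sp$n_others, 3)
  expect_equal(sp$median_pr, 5.25)
  expect_equal(sp$median_others, 8)
  expect_error(split_pr_vs_others(comms, character(), bm), "non-empty")
})

test_that("PR-group medians fall below the Others on default screens", {
  lower <- vapply(1:6, function(s) {
    scr <- generate_screen(generator_config(), seed = 800 + s)
    train <- preprocess_screen(scr$train, "mean")
    agg <- aggregate_by_box(train)
    agg <- agg[!(agg$treatment %in% train$controls), ]
    sp <- split_pr_vs_others(
      scr$communities[scr$communities$community_id %in% agg$community_id, ],
      pr_strains(generator_config()), agg)
    sp$median_pr < sp$median_others
  }, logical(1))
  expect_true(all(lower))
})

test_that("tail communities equal a brute-force filter and carry the synergy", {
  scr <- generate_screen(generator_config(), seed = 807)
  train <- preprocess_screen(scr$train, "mean")
  agg <- aggregate_by_box(train)
  agg <- agg[!(agg$treatment %in% train$controls), ]
  sp <- split_pr_vs_others(
    scr$communities[scr$communities$community_id %in% agg$community_id, ],
    pr_strains(generator_config()), agg)
  thr <- 6.5
  tail_ids <- tail_communities(sp, agg, thr)
  manual <- agg$community_id[agg$community_id %in%
    sp$groups$community_id[sp$groups$group == "Others"] &
    agg$median_pathogen < thr]
  expect_setequal(tail_ids, sort(manual))
  expect_length(tail_communities(sp, agg, min(agg$median_pathogen) - 1), 0)
  # tail Others communities are enriched for the intermediate strain
  if (length(tail_ids) >= 2) {
    freq <- strain_frequency_in(scr$communities, ids = tail_ids)
    n_tail <- length(tail_ids)
    frac_int <- freq$count[freq$strain_id == "strain_04"] / n_tail
    expect_gt(frac_int, 5 / 35) # well above the background prevalence
  }
})

test_that("strain frequencies count membership and conserve k * n", {
  comms <- list(x = c("A", "B"), y = c("A", "C"))
  f <- strain_frequency_in(comms)
  expect_equal(setNames(f$count, f$strain_id), c(A = 2L, B = 1L, C = 1L))
  expect_equal(sum(f$count), 2 * 2)
  empty <- strain_frequency_in(list(), pool = strain_pool(c("A", "B")))
  expect_equal(empty$count, c(0L, 0L))
})

test_that("Bonferroni arithmetic and letters match the pairwise matrix", {
  expect_equal(min(1, 0.004 * 15), 0.06)
  # letter display against randomized significance matrices
  set.seed(20)
  for (r in 1:25) {
    k <- sample(3:6, 1)
    trts <- paste0("t", seq_len(k))
    sig <- matrix(FALSE, k, k, dimnames = list(trts, trts))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      s <- runif(1) < 0.4
      sig[i, j] <- s; sig[j, i] <- s
    }
    letters_out <- letter_display(sig)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      shares <- length(intersect(strsplit(letters_out[i], "")[[1]],
                                 strsplit(letters_out[j], "")[[1]])) > 0
      # shares a letter <=> not significantly different
      expect_equal(shares, !sig[i, j],
                   info = sprintf("rep %d pair %s-%s", r, trts[i], trts[j]))
    }
  }
})

test_that("validation contrasts detect large separations with distinct letters", {
  cfg <- generator_config()
  treatments <- list(axenic = character(), deep = c("strain_01", "strain_02"))
  v <- generate_validation_experiment(cfg, treatments, 6, seed = 900)
  lg <- log10_transform(partition_ambiguous(v$data))
  res <- validation_contrasts(lg, exclude_treatments = character())
  expect_equal(res$family_size, 1)
  row <- res$contrasts[1, ]
  expect_lt(row$p_bonferroni, 0.05)
  expect_equal(abs(row$estimate), 3.87, tolerance = 0.8)
  expect_length(intersect(strsplit(res$letters[["axenic"]], "")[[1]],
                          strsplit(res$letters[["deep"]], "")[[1]]), 0)
  # family-size accounting equals the declared list, never recomputed
  fam <- data.frame(a = "axenic", b = "deep")
  res2 <- validation_contrasts(lg, family = fam,
                               exclude_treatments = character())
  expect_equal(res2$family_size, 1)
})

test_that("identical treatments share letters at close to the nominal rate", {
  cfg <- small_null_config()
  shared <- vapply(1:40, function(s) {
    treatments <- list(t1 = c("strain_06", "strain_07"),
                       t2 = c("strain_08", "strain_09"))
    v <- generate_validation_experiment(cfg, treatments, 4, seed = 950 + s)
    lg <- log10_transform(v$data)
    res <- validation_contrasts(lg, exclude_treatments = character())
    length(intersect(strsplit(res$letters[["t1"]], "")[[1]],
                     strsplit(res$letters[["t2"]], "")[[1]])) > 0
  }, logical(1))
  # null rate of shared letters ~95%; binomial slack at 40 replicates
  expect_gte(mean(shared), 0.85)
})

test_that("the synergy contrast recovers about one order of magnitude", {
  cfg <- generator_config()
  treatments <- list(axenic = character(), intermediate = "strain_04",
                     weak = "strain_05",
                     combo = c("strain_04", "strain_05"))
  est <- vapply(1:5, function(s) {
    v <- generate_validation_experiment(cfg, treatments, 6, seed = 970 + s)
    lg <- log10_transform(partition_ambiguous(v$data))
    res <- validation_contrasts(lg, exclude_treatments = "axenic")
    ct <- res$contrasts
    row <- ct[(ct$a == "combo" & ct$b == "intermediate") |
                (ct$a == "intermediate" & ct$b == "combo"), ]
    est <- row$estimate
    if (row$a == "combo") est else -est
  }, numeric(1))
  # combo minus intermediate: delta_weak + gamma = -1.3
  expect_lt(abs(mean(est) - (-1.3)), 0.45)
})
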