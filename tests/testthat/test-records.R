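test_that("log10 transform converts values once and guards preconditions", {
  sd_ <- tiny_screen()
  lg <- log10_transform(sd_)
  expect_equal(lg$plants$pathogen_cfu[1], 5)
  expect_equal(lg$strains$cfu_per_g[1], 7)
  expect_error(log10_transform(lg), "already")
  bad <- tiny_screen()
  bad$strains$cfu_per_g[1] <- 0
  expect_error(log10_transform(bad), "floor")
  # round-trip for floor-like and extreme values
  for (x in c(log10(0.09 * 25000), 4, 9)) {
    one <- tiny_screen()
    one$plants$pathogen_cfu[1] <- 10^x
    expect_equal(log10_transform(one)$plants$pathogen_cfu[1], x)
  }
})

test_that("detection floor uses the 0.09 sentinel with count arithmetic", {
  tab <- tibble::tibble(raw_count = c(12, NA, 0), conversion = c(5e4, 5e4, 2e5))
  out <- apply_detection_floor(tab)
  expect_equal(out$cfu_per_g, c(12 * 5e4, 0.09 * 5e4, 0.09 * 2e5))
  expect_equal(out$flag, c("detected", "below_detection", "below_detection"))
  # all-detected table passes through unchanged
  all_det <- tibble::tibble(raw_count = c(3, 8), conversion = c(1e3, 1e3))
  expect_equal(apply_detection_floor(all_det)$cfu_per_g, c(3e3, 8e3))
  expect_error(apply_detection_floor(tibble::tibble(raw_count = 1,
                                                    conversion = NA)),
               "conversion")
})

test_that("ambiguous partitioning splits pooled counts and conserves totals", {
  sd_ <- tiny_screen()
  # pool strains A and B of plant p1 at 6e7 total
  sd_$strains$cfu_per_g[1:2] <- 6e7
  sd_$strains$flag[1:2] <- "ambiguous"
  sd_$strains$ambiguity_group[1:2] <- "p1_amb"
  before <- total_commensal(sd_)
  part <- partition_ambiguous(sd_)
  expect_equal(part$strains$cfu_per_g[1:2], c(3e7, 3e7))
  after <- total_commensal(part)
  expect_equal(before$total_cfu, after$total_cfu)
  # three-way group
  sd3 <- tiny_screen()
  sd3$strains$cfu_per_g[1:3] <- 9e6
  sd3$strains$flag[1:3] <- "ambiguous"
  sd3$strains$ambiguity_group[1:3] <- "p1_amb"
  expect_equal(partition_ambiguous(sd3)$strains$cfu_per_g[1:3], rep(3e6, 3))
  # undersized group is a data error
  sd1 <- tiny_screen()
  sd1$strains$ambiguity_group[1] <- "solo"
  expect_error(partition_ambiguous(sd1), "size")
})

test_that("total commensal sums community strains only, with axenic empty", {
  sd_ <- tiny_screen()
  tc <- total_commensal(sd_)
  expect_equal(tc$total_cfu[tc$plant_id == "p1"], 4e7)
  expect_equal(tc$total_cfu[tc$plant_id == "p5"], 0)
  expect_equal(tc$n_strains[tc$plant_id == "p5"], 0L)
  # floors participate in the sum like real counts
  sdf <- tiny_screen()
  sdf$strains$cfu_per_g[3] <- 10^3.5
  sdf$strains$flag[3] <- "below_detection"
  expect_equal(total_commensal(sdf)$total_cfu[1], 1e7 + 2e7 + 10^3.5)
})

test_that("normalization centers by per-experiment axenic controls", {
  lg <- log10_transform(tiny_screen())
  nm <- normalize_pathogen(lg, center = "median")
  ax_med <- median(c(8.2, 8.4))
  expect_equal(nm$plants$pathogen_norm,
               nm$plants$pathogen_cfu - ax_med)
  # mean vs median centering differ by the axenic skew
  lg2 <- lg
  lg2$plants$pathogen_cfu[5] <- 6 # skew the axenic pair
  m1 <- normalize_pathogen(lg2, "median")$plants$pathogen_norm[1]
  m2 <- normalize_pathogen(lg2, "mean")$plants$pathogen_norm[1]
  expect_equal(m1 - m2, mean(c(6, 8.4)) - median(c(6, 8.4)))
  # translation equivariance
  sh <- lg
  sh$plants$pathogen_cfu <- sh$plants$pathogen_cfu + 2
  n0 <- normalize_pathogen(lg, "median")$plants$pathogen_norm
  n2 <- normalize_pathogen(sh, "median")$plants$pathogen_norm
  expect_equal(n0, n2)
  # missing axenic controls are an error
  noax <- lg
  noax$plants$treatment[5:6] <- "c2"
  noax$plants$community_id[5:6] <- "c2"
  expect_error(normalize_pathogen(noax), "axenic")
})

test_that("Tukey fences flag with a closed interval and type-7 quartiles", {
  v <- c(1, 2, 3, 100)
  expect_equal(flag_outliers(v), c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers(c(5, 5.1, 5.2, 4.9, 5.05))))
  # boundary value exactly at Q3 + 1.5 IQR is NOT flagged (closed interval):
  # for c(0,1,2,3,x>=3), type-7 quartiles are 1 and 3, so the fence sits at 6
  expect_false(flag_outliers(c(0, 1, 2, 3, 6))[5])
  expect_true(flag_outliers(c(0, 1, 2, 3, 6.001))[5])
  # invariant to group order and labels
  vals <- c(rnorm(20), 50, rnorm(20, 10), -40)
  grp1 <- rep(c("a", "b"), each = 21)
  perm <- sample(length(vals))
  f1 <- flag_outliers(vals, grp1)
  f2 <- flag_outliers(vals[perm], grp1[perm])
  expect_equal(f1[perm], f2)
})

test_that("box aggregation takes medians after exclusions", {
  lg <- log10_transform(tiny_screen())
  lg$plants$pathogen_cfu <- c(5, 6, 7, 8, 8.2, 8.4)
  agg <- aggregate_by_box(lg)
  expect_equal(agg$median_pathogen[agg$box_id == "b1"], 5.5)
  expect_equal(sort(agg$n_plants), c(2, 2, 2))
  # sort-and-middle oracle on 4 values
  lg4 <- lg
  lg4$plants <- lg4$plants[1:4, ]
  lg4$plants$box_id <- "b1"
  lg4$plants$treatment <- "c1"
  lg4$plants$community_id <- "c1"
  lg4$plants$pathogen_cfu <- c(8, 5, 7, 6)
  expect_equal(aggregate_by_box(lg4)$median_pathogen, mean(c(6, 7)))
  # excluded plants drop out
  ex <- exclude_plants(lg, "p2", "disturbed")
  expect_equal(aggregate_by_box(ex)$median_pathogen[1], 5)
  expect_true(ex$plants$excluded[2])
})
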