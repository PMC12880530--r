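test_that("identical parameters give byte-identical cohorts", {
  p <- fast_params(n_units = 6, seed = 99L, plaque_lambda0 = 5e-7)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(s1$units, f1)
  write_swc(s2$units, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$spots, s2$spots)
  expect_identical(s1$dyshoric, s2$dyshoric)
})

test_that("branch_prob = 0 grows unbranched units labeling LMA and D0", {
  set.seed(1)
  p <- fast_params(branch_prob = 0)
  u <- label_depths(generate_unit_geometry(p, 1))
  expect_true(all(u$segments$label %in% c("LMA", "D0")))
})

test_that("tapering respects the 8 um inclusion floor", {
  set.seed(2)
  p <- fast_params(taper = 0.6, max_depth = 6, branch_prob = 1,
                   seg_len_mean_um = 60, seg_len_sd_um = 5)
  u <- generate_unit_geometry(p, 1, root_diameter_um = 40)
  expect_gte(min(2 * u$nodes$radius), 8)
  expect_equal(max(2 * u$nodes$radius), 40)
})

test_that("with no skip or white-matter variants, positivity is a
           contiguous prefix of the depth chain", {
  p <- fast_params(n_units = 400, p_unit_abeta = 1, p_skip = 0,
                   p_wm_confined = 0, seed = 17L)
  s <- simulate_cohort(p)
  for (u in s$units) {
    seg <- u$segments
    depth <- grepl("^D[0-6]$|DEEPER", seg$label)
    pos_r <- label_rank(seg$label[depth & seg$abeta_positive])
    neg_r <- label_rank(seg$label[depth & !seg$abeta_positive])
    if (length(pos_r) && length(neg_r)) {
      expect_lt(max(pos_r), min(neg_r))
    }
    expect_false(detect_skip_pattern(u))
  }
})

test_that("smooth-muscle loss is nested inside amyloid positivity and
           contiguous from its onset", {
  p <- fast_params(n_units = 300, p_unit_abeta = 1, p_sma_loss = 1,
                   seed = 23L)
  s <- simulate_cohort(p)
  n_lost <- 0
  for (u in s$units) {
    seg <- u$segments
    lost <- !seg$sma_present
    expect_true(all(seg$abeta_positive[lost]))
    if (any(lost)) {
      n_lost <- n_lost + 1
      onset <- min(label_rank(seg$label[lost]))
      # loss covers every positive segment at or below the onset
      expect_true(all(lost[seg$abeta_positive &
                             label_rank(seg$label) >= onset]))
    }
  }
  expect_gt(n_lost, 250)
})

test_that("the SMA onset distribution is recovered when every category
           is available", {
  # force all depth labels positive so no onset category is restricted
  p <- fast_params(n_units = 600, p_unit_abeta = 1, p_lma_abeta = 1,
                   p_sma_loss = 1, p_skip = 0, p_wm_confined = 0,
                   front_reach_probs = c(1, 1, 1, 1, 1, 1, 1),
                   sma_onset_dist = c(LMA = 0.5, D0 = 0.3, D1 = 0.15,
                                      deeper = 0.05),
                   branch_prob = 1, max_depth = 3, seed = 29L)
  s <- simulate_cohort(p)
  onset <- vapply(s$units, most_superficial_sma_loss, character(1))
  cat_of <- function(l) {
    r <- label_rank(l)
    ifelse(l == "LMA", "LMA", ifelse(r == 1, "D0",
                                     ifelse(r == 2, "D1", "deeper")))
  }
  # units whose tree lacks a D1/deeper cannot draw those categories;
  # restrict the oracle to units possessing all labels
  has_all <- vapply(s$units, function(u)
    all(c("LMA", "D0", "D1") %in% u$segments$label) &&
      any(label_rank(u$segments$label) > 2), logical(1))
  obs <- table(factor(cat_of(onset[has_all]),
                      levels = c("LMA", "D0", "D1", "deeper")))
  n <- sum(obs)
  expected <- c(0.5, 0.3, 0.15, 0.05)
  for (k in 1:4) {
    sd3 <- 3 * sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(obs[k] / n - expected[k]), sd3 + 1e-9)
  }
})

test_that("plaque sampling follows the Poisson oracle without vessels
           and is empty at zero intensity", {
  p0 <- fast_params(plaque_lambda0 = 0)
  set.seed(1)
  expect_equal(nrow(sample_plaques(list(), p0)), 0)
  lam <- 2e-6
  p1 <- fast_params(plaque_lambda0 = lam)
  vol_cortex <- prod(p1$slab_dims_um[1:2]) * p1$cortex_thickness_um
  set.seed(4)
  counts <- replicate(20, nrow(sample_plaques(list(), p1)))
  mu <- lam * vol_cortex
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 20))
  s <- sample_plaques(list(), p1)
  expect_true(all(s$z_um < p1$cortex_thickness_um))
  expect_true(all(s$radius_um > 0))
})

test_that("dyshoric placement honors the D0 share and its degenerate
           cases", {
  p <- fast_params(p_dyshoric_unit = 0)
  set.seed(3)
  s <- simulate_cohort(fast_params(n_units = 30, p_dyshoric_unit = 0,
                                   seed = 5L))
  expect_equal(nrow(s$dyshoric), 0)
  s2 <- simulate_cohort(fast_params(n_units = 60, p_unit_abeta = 1,
                                    p_dyshoric_unit = 1,
                                    dyshoric_d0_share = 1,
                                    p_penetrate_wm = 0, seed = 6L))
  expect_gt(nrow(s2$dyshoric), 0)
  expect_true(all(s2$dyshoric$label == "D0"))
  # sleeves sit on amyloid-positive cortical segments
  for (i in seq_len(nrow(s2$dyshoric))) {
    u <- s2$units[[s2$dyshoric$unit_id[i]]]
    j <- match(s2$dyshoric$seg_id[i], u$segments$seg_id)
    expect_true(u$segments$abeta_positive[j])
  }
})

test_that("designated white-matter-penetrating units reach the medulla", {
  p <- fast_params(n_units = 120, p_penetrate_wm = 0.4, seed = 44L)
  s <- simulate_cohort(p)
  flagged <- vapply(s$units, function(u) isTRUE(u$penetrates_wm),
                    logical(1))
  reaches <- vapply(s$units, function(u)
    any(u$nodes$z > p$cortex_thickness_um), logical(1))
  expect_identical(flagged, reaches)
})
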