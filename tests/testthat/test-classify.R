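# crafted tube volumes for the segment classifiers (no PSF, no noise)
tube_volume <- function(radius = 12, abeta_span = NULL, sma_gap = NULL,
                        v = 2, dims = c(110L, 60L, 60L)) {
  sma <- array(0, dims)
  ab <- array(0, dims)
  poly <- cbind(60, 60, seq(4, 212, by = 4))
  ctr <- caa3d:::world_to_vox(poly, v)
  keep <- rep(TRUE, nrow(poly))
  if (!is.null(sma_gap)) {
    keep <- !(poly[, 3] > sma_gap[1] & poly[, 3] < sma_gap[2])
  }
  cpp_stamp_spheres(sma, dims, ctr[keep, , drop = FALSE],
                    rep(radius / v, sum(keep)), 30000)
  if (!is.null(abeta_span)) {
    sel <- poly[, 3] >= abeta_span[1] & poly[, 3] <= abeta_span[2]
    at <- caa3d:::world_to_vox(poly[sel, , drop = FALSE], v)
    n <- nrow(at)
    cpp_stamp_cylinders(ab, dims, at[-n, , drop = FALSE],
                        at[-1, , drop = FALSE],
                        rep((radius + 4) / v, n - 1), 28000)
  }
  list(volume = two_channel_volume(sma, ab, v),
       polyline = poly, radii = rep(radius, nrow(poly)))
}

test_that("a zero amyloid channel classifies negative with zero coverage", {
  tv <- tube_volume()
  res <- classify_segment_abeta(tv$volume, tv$polyline[5:45, ],
                                tv$radii[5:45], 5000)
  expect_false(res$positive)
  expect_equal(res$coverage, 0)
})

test_that("a deposit sleeve over 60% of the length is positive with
           matching coverage", {
  tv <- tube_volume(abeta_span = c(40, 160))   # 120 of 200 um
  res <- classify_segment_abeta(tv$volume, tv$polyline[2:52, ],
                                tv$radii[2:52], 5000)
  expect_true(res$positive)
  expect_gt(res$coverage, 0.5)
  expect_lt(res$coverage, 0.7)
  expect_gt(res$longest_run_um, 100)
})

test_that("raising the intensity threshold never flips negative to
           positive", {
  tv <- tube_volume(abeta_span = c(80, 110))
  poly <- tv$polyline[2:52, ]; radii <- tv$radii[2:52]
  lo <- classify_segment_abeta(tv$volume, poly, radii, 4000)
  hi <- classify_segment_abeta(tv$volume, poly, radii, 20000)
  vhi <- classify_segment_abeta(tv$volume, poly, radii, 40000)
  expect_gte(lo$coverage, hi$coverage)
  expect_gte(hi$coverage, vhi$coverage)
  expect_false(vhi$positive)
})

test_that("a segment outside the volume raises an out-of-bounds error", {
  tv <- tube_volume()
  far <- cbind(400, 400, seq(10, 100, by = 4))
  expect_error(classify_segment_abeta(tv$volume, far, rep(10, nrow(far)),
                                      5000),
               "outside volume bounds")
})

test_that("smooth-muscle gaps classify by the inclusive gap rule", {
  cont <- tube_volume()
  res <- classify_segment_sma(cont$volume, cont$polyline[2:52, ],
                              cont$radii[2:52], 5000)
  expect_true(res$present)
  gap50 <- tube_volume(sma_gap = c(80, 150))
  res50 <- classify_segment_sma(gap50$volume, gap50$polyline[2:52, ],
                                gap50$radii[2:52], 5000, gap_max_um = 20)
  expect_false(res50$present)
  expect_gt(res50$longest_gap_um, 30)
  # a gap of exactly gap_max still counts as present
  res_eq <- classify_segment_sma(gap50$volume, gap50$polyline[2:52, ],
                                 gap50$radii[2:52], 5000,
                                 gap_max_um = res50$longest_gap_um)
  expect_true(res_eq$present)
})

test_that("unit status is any positive segment, including LMA only", {
  expect_false(unit_abeta_status(c(FALSE, FALSE)))
  df <- status_df(c("LMA", "D0"), c(NA, 1L), c(TRUE, FALSE))
  expect_true(unit_abeta_status(df))
})

test_that("vascular load reproduces printed arithmetic and boundary
           classes", {
  make_units <- function(n_pos, n_tot) {
    status_df(rep("D0", n_tot), rep(NA_integer_, n_tot),
              c(rep(TRUE, n_pos), rep(FALSE, n_tot - n_pos)),
              unit_id = seq_len(n_tot))
  }
  frontal <- vascular_load(make_units(513, 865))
  expect_equal(round(100 * frontal$load_fraction, 1), 59.3)
  expect_identical(frontal$load_class, "moderate")
  occipital <- vascular_load(make_units(591, 774))
  expect_equal(round(100 * occipital$load_fraction, 1), 76.4)
  expect_identical(occipital$load_class, "high")
  expect_identical(vascular_load(make_units(40, 100))$load_class,
                   "moderate")
  expect_identical(vascular_load(make_units(60, 100))$load_class,
                   "moderate")
  expect_identical(vascular_load(make_units(39, 100))$load_class, "low")
  expect_identical(vascular_load(make_units(61, 100))$load_class, "high")
})

test_that("per-segment rates use the possessing-units denominator by
           default, with the all-positive alternative", {
  df <- rbind(
    status_df(c("D0", "D1"), c(NA, 1L), c(TRUE, TRUE), unit_id = 1L),
    status_df(c("D0"), NA_integer_, TRUE, unit_id = 2L),
    status_df(c("D0", "D1"), c(NA, 1L), c(TRUE, FALSE), unit_id = 3L))
  r1 <- vascular_load(df)$per_segment_rates
  expect_equal(r1$rate[r1$label == "D1"], 0.5)   # 1 of 2 possessing
  r2 <- vascular_load(df, denominator = "all_positive")$per_segment_rates
  expect_equal(r2$rate[r2$label == "D1"], 1 / 3)
})

test_that("the most superficial SMA-lost segment follows the label
           order", {
  df <- tibble::tibble(label = c("LMA", "D0", "D1"),
                       sma_present = c(TRUE, FALSE, FALSE))
  expect_identical(most_superficial_sma_loss(df), "D0")
  df2 <- tibble::tibble(label = c("LMA", "D0"),
                        sma_present = c(FALSE, TRUE))
  expect_identical(most_superficial_sma_loss(df2), "LMA")
  df3 <- tibble::tibble(label = c("LMA", "D0"),
                        sma_present = c(TRUE, TRUE))
  expect_true(is.na(most_superficial_sma_loss(df3)))
})

test_that("skip-pattern detection matches a brute-force ancestor scan on
           random status assignments", {
  expect_true(detect_skip_pattern(status_df(
    c("LMA", "D0", "D0-D1", "D1", "D1-D2", "D2", "D2-D3", "D3"),
    c(NA, 1L, 2L, 3L, 4L, 5L, 6L, 7L),
    c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))))
  expect_false(detect_skip_pattern(status_df(
    c("LMA", "D0", "D0-D1", "D1"),
    c(NA, 1L, 2L, 3L),
    c(FALSE, TRUE, TRUE, TRUE))))
  # brute force: enumerate full ancestor label sets per segment
  brute <- function(df) {
    rank <- label_rank(df$label)
    anc <- function(i) {
      out <- integer(0)
      a <- match(df$parent_seg[i], df$seg_id)
      while (!is.na(a)) { out <- c(out, a); a <- match(df$parent_seg[a],
                                                      df$seg_id) }
      out
    }
    for (i in which(df$abeta_positive & df$label != "LMA")) {
      A <- anc(i)
      A <- A[df$label[A] != "LMA"]
      if (any(!df$abeta_positive[A] & rank[A] < rank[i] - 1e-9)) {
        return(TRUE)
      }
    }
    FALSE
  }
  set.seed(77)
  p <- fast_params(n_units = 1)
  skel <- lapply(1:5, function(i)
    label_depths(generate_unit_geometry(p, i))$segments)
  for (rep in 1:200) {
    seg <- skel[[sample(5, 1)]]
    df <- status_df(seg$label, seg$parent_seg,
                    runif(nrow(seg)) < 0.4)
    df$seg_id <- seg$seg_id
    expect_identical(detect_skip_pattern(df), brute(df))
  }
})

test_that("whole-sample classification is deterministic", {
  p <- cohort_params(slab_dims_um = c(400, 400, 240),
                     cortex_thickness_um = 180, n_units = 4,
                     voxel_size_um = 4, seg_len_mean_um = 80,
                     seg_len_sd_um = 15, step_um = 12, max_depth = 2,
                     dir_noise = 0.1, down_bias = 0.35,
                     plaque_lambda0 = 0, artifact_puncta_density = 0,
                     p_unit_abeta = 1, lma_len_um = 48, seed = 55L)
  s <- simulate_cohort(p)
  vol <- rasterize(s)
  r1 <- classify_units(vol, s$units, 5000)
  r2 <- classify_units(vol, s$units, 5000)
  expect_identical(r1$status, r2$status)
  expect_identical(r1$load$per_segment_rates, r2$load$per_segment_rates)
})
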