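empty_sample <- function(params) {
  structure(list(
    units = list(),
    spots = tibble::tibble(spot_id = integer(), x_um = numeric(),
                           y_um = numeric(), z_um = numeric(),
                           radius_um = numeric()),
    dyshoric = tibble::tibble(unit_id = integer(), seg_id = integer(),
                              label = character(), start_um = numeric(),
                              length_um = numeric(), r_in_um = numeric(),
                              r_out_um = numeric()),
    params = params, seed = params$seed), class = "gt_sample")
}

raster_params <- function(...) {
  args <- list(slab_dims_um = c(240, 240, 200),
               cortex_thickness_um = 150, n_units = 1, voxel_size_um = 2,
               artifact_puncta_density = 0, plaque_lambda0 = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_params, args)
}

# a labeled straight tube with truth columns set by the assignment ops
tube_sample <- function(params, radius = 16, abeta = FALSE,
                        sma_gap = NULL) {
  u <- label_depths(chain_unit(x = 120, y = 120, z_top = -40,
                               z_bottom = 190, radius = radius, step = 8),
                    cortex_z = params$cortex_thickness_um)
  u <- assign_abeta(u, params, positive = abeta)
  u <- assign_sma_loss(u, params)
  s <- empty_sample(params)
  s$units <- list(u)
  s
}

test_that("an empty sample rasterizes to pure background", {
  p <- raster_params()
  set.seed(1)
  vol <- rasterize(empty_sample(p))
  expect_true(all(vol$sma == p$imaging$background))
  expect_true(all(vol$abeta == p$imaging$background))
})

test_that("the volume cap refuses oversized rasters with a voxel hint", {
  p <- raster_params(voxel_size_um = 0.25)
  expect_error(rasterize(empty_sample(p), cap_voxels = 64^3),
               "voxel_size_um")
})

test_that("a rasterized 32 um tube is recovered within one voxel by the
           distance-transform radius estimator", {
  p <- raster_params()
  set.seed(2)
  s <- tube_sample(p, radius = 16)
  vol <- rasterize(s)
  seg <- s$units[[1]]$segments
  d0 <- seg$polyline[[which(seg$label == "D0")[1]]]
  prof <- estimate_radius_profile(vol, d0[3:(nrow(d0) - 3), ], 15000)
  expect_lt(abs(2 * median(prof) - 32), p$voxel_size_um + 1e-9)
})

test_that("the radius estimator is scale-consistent across voxel sizes", {
  for (v in c(2, 4)) {
    p <- raster_params(voxel_size_um = v)
    set.seed(3)
    s <- tube_sample(p, radius = 14)
    vol <- rasterize(s)
    seg <- s$units[[1]]$segments
    d0 <- seg$polyline[[which(seg$label == "D0")[1]]]
    prof <- estimate_radius_profile(vol, d0[3:(nrow(d0) - 3), ], 15000)
    expect_lt(abs(2 * median(prof) - 28), v + 1e-9)
  }
})

test_that("a centerline through background yields a zero radius profile", {
  p <- raster_params()
  set.seed(4)
  vol <- rasterize(tube_sample(p, radius = 12))
  off <- cbind(40, 40, seq(20, 120, by = 4))   # far from the tube
  prof <- estimate_radius_profile(vol, off, 5000)
  expect_true(all(prof == 0))
})

test_that("spot detection recovers isolated blobs and merges close ones", {
  v <- 2
  dims <- c(80L, 100L, 100L)
  blank <- two_channel_volume(array(0, dims), array(0, dims), v)
  expect_equal(nrow(detect_spots(blank, 50, 1000)), 0)
  ab <- array(0, dims)
  truth <- rbind(c(60, 60, 60), c(160, 60, 60))
  cpp_stamp_spheres(ab, dims, caa3d:::world_to_vox(truth, v),
                    rep(25 / v, 2), 20000)
  vol <- two_channel_volume(array(0, dims), ab, v)
  sp <- detect_spots(vol, 50, 1000)
  expect_equal(nrow(sp), 2)
  for (k in 1:2) {
    d <- min(sqrt((sp$x_um - truth[k, 1])^2 + (sp$y_um - truth[k, 2])^2 +
                    (sp$z_um - truth[k, 3])^2))
    expect_lt(d, 10)
  }
  # two blobs 20 um apart fall inside the suppression radius -> one spot
  ab2 <- array(0, dims)
  close_truth <- rbind(c(90, 100, 80), c(110, 100, 80))
  cpp_stamp_spheres(ab2, dims, caa3d:::world_to_vox(close_truth, v),
                    rep(20 / v, 2), 20000)
  sp2 <- detect_spots(two_channel_volume(array(0, dims), ab2, v), 50, 1000)
  expect_equal(nrow(sp2), 1)
  expect_error(detect_spots(blank, 3, 100), "2 voxels")
})

test_that("dual-channel puncta are flagged as artifacts while true spots
           survive the ratio filter", {
  p <- raster_params(slab_dims_um = c(400, 400, 240),
                     cortex_thickness_um = 180,
                     artifact_puncta_density = 4e-6,
                     imaging = list(puncta_sigma_um = 10))
  set.seed(6)
  s <- empty_sample(p)
  s$spots <- tibble::tibble(spot_id = 1:3,
                            x_um = c(100, 300, 200),
                            y_um = c(100, 300, 120),
                            z_um = c(60, 120, 150),
                            radius_um = 20)
  vol <- rasterize(s)
  det <- exclude_artifacts(detect_spots(vol, 50, quality_min = 1500),
                           vol, 50, ratio_alpha = 0.8)
  truth_xyz <- as.matrix(s$spots[, c("x_um", "y_um", "z_um")])
  near_truth <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt(rowSums((truth_xyz -
                        matrix(unlist(det[i, c("x_um", "y_um", "z_um")]),
                               3, 3, byrow = TRUE))^2))) < 15
  }, logical(1))
  # every true spot detected and kept; every punctum detection flagged
  expect_gte(sum(near_truth & !det$is_artifact), 3)
  expect_true(all(det$is_artifact[!near_truth]))
  expect_gt(sum(!near_truth), 0)   # the filter was actually exercised
})

test_that("spot exclusion boundary behavior matches the ratio rule", {
  sp <- tibble::tibble(x_um = 50, y_um = 50, z_um = 50, radius_um = 25,
                       quality = 1000, log_response = 1)
  dims <- c(50L, 50L, 50L)
  zero_sma <- two_channel_volume(array(0, dims), array(0, dims), 2)
  out <- exclude_artifacts(sp, zero_sma, 50, 0.8)
  expect_false(out$is_artifact)
})
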