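test_that("point-to-polyline distance handles laterals, endpoints and a
           dense-sampling oracle", {
  seg <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(point_polyline_distance(c(50, 30, 0), seg), 30)
  expect_equal(point_polyline_distance(c(130, 0, 40), seg),
               sqrt(30^2 + 40^2))
  set.seed(8)
  for (i in 1:100) {
    poly <- apply(matrix(rnorm(15, sd = 30), ncol = 3), 2, cumsum)
    pt <- rnorm(3, sd = 50)
    dense <- do.call(rbind, lapply(seq_len(nrow(poly) - 1), function(k) {
      t <- seq(0, 1, length.out = 1 + ceiling(
        sqrt(sum((poly[k + 1, ] - poly[k, ])^2)) / 0.1))
      poly[rep(k, length(t)), ] + outer(t, poly[k + 1, ] - poly[k, ])
    }))
    oracle <- min(sqrt(rowSums(sweep(dense, 2, pt)^2)))
    expect_lt(abs(point_polyline_distance(pt, poly) - oracle), 0.05)
  }
})

test_that("the perivascular band is inclusive at both bounds", {
  u <- label_depths(chain_unit(x = 0, y = 0, z_top = -40, z_bottom = 400,
                               radius = 10))
  mk <- function(d) tibble::tibble(x_um = d, y_um = 0, z_um = 200,
                                   radius_um = 12)
  expect_equal(nrow(perivascular_spots(u, mk(5))), 0)
  expect_equal(nrow(perivascular_spots(u, mk(10))), 1)
  expect_equal(nrow(perivascular_spots(u, mk(55))), 1)
  expect_equal(nrow(perivascular_spots(u, mk(100))), 1)
  expect_equal(nrow(perivascular_spots(u, mk(150))), 0)
})

test_that("band filtering agrees exactly with a brute-force all-pairs
           check on a synthetic cohort", {
  p <- fast_params(n_units = 25, plaque_lambda0 = 1.5e-6,
                   p_penetrate_wm = 0.2, seed = 61L)
  s <- simulate_cohort(p)
  tab <- perivascular_density_table(s$units, s$spots,
                                    p$cortex_thickness_um)
  keep <- exclude_wm_units(s$units, p$cortex_thickness_um)
  expect_equal(nrow(tab), length(keep))
  for (u in keep) {
    d <- vapply(seq_len(nrow(s$spots)), function(i)
      point_polyline_distance(unlist(s$spots[i, c("x_um", "y_um",
                                                  "z_um")]), u),
      numeric(1))
    brute_n <- sum(d >= 10 & d <= 100)
    expect_identical(tab$n_spots_in_band[tab$unit_id == u$unit_id],
                     as.integer(brute_n))
  }
})

test_that("white-matter exclusion drops penetrating and flagged units
           with the expected retention rate", {
  u_in <- chain_unit(z_bottom = 400, unit_id = 1L)
  u_out <- chain_unit(z_bottom = 520, unit_id = 2L)
  kept <- exclude_wm_units(list(u_in, u_out), 500)
  expect_equal(vapply(kept, function(u) u$unit_id, integer(1)), 1L)
  u_flag <- chain_unit(unit_id = 3L)
  u_flag$excluded_reason <- "perivascular-artifact"
  expect_length(exclude_wm_units(list(u_in, u_flag), 500), 1)
  p <- fast_params(n_units = 400, p_penetrate_wm = 0.3, seed = 71L)
  s <- simulate_cohort(p)
  kept_frac <- length(exclude_wm_units(s$units, p$cortex_thickness_um)) /
    length(s$units)
  expect_lt(abs(kept_frac - 0.7), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("plaque density is count over filament length", {
  u <- label_depths(chain_unit(z_top = -50, z_bottom = 1500, radius = 10))
  len <- sum(u$segments$length_um)
  spots30 <- tibble::tibble(x_um = rep(40, 30), y_um = 100,
                            z_um = seq(10, 1400, length.out = 30))
  rec <- plaque_density(u, spots30)
  expect_equal(rec$density_per_um, 30 / len)
  expect_equal(plaque_density(u, spots30[0, ])$density_per_um, 0)
  rec2 <- plaque_density(u, rbind(spots30, spots30))
  expect_equal(rec2$density_per_um, 2 * rec$density_per_um)
  # magnitude sanity: 30 spots on a 1550 um filament ~ 0.0194 n/um
  expect_equal(30 / 1550, 0.019355, tolerance = 1e-4)
})

test_that("density is invariant to re-sampling the same centerline", {
  p <- fast_params(n_units = 8, plaque_lambda0 = 1.5e-6, seed = 81L)
  s <- simulate_cohort(p)
  tab1 <- perivascular_density_table(s$units, s$spots,
                                     p$cortex_thickness_um)
  resampled <- lapply(s$units, function(u) {
    u$segments$polyline <- lapply(seq_len(nrow(u$segments)), function(j) {
      rs <- caa3d:::resample_polyline(u$segments$polyline[[j]], 3)
      rs$points
    })
    u
  })
  tab2 <- perivascular_density_table(resampled, s$spots,
                                     p$cortex_thickness_um)
  expect_equal(tab1$n_spots_in_band, tab2$n_spots_in_band)
  expect_equal(tab1$density_per_um, tab2$density_per_um,
               tolerance = 0.005)
})

test_that("dyshoric flagging finds the rendered sleeve and only it, and
           ignores spherical blobs near the wall", {
  p <- cohort_params(slab_dims_um = c(300, 300, 260),
                     cortex_thickness_um = 200, n_units = 1,
                     voxel_size_um = 2, plaque_lambda0 = 0,
                     artifact_puncta_density = 0, seed = 91L)
  u <- label_depths(chain_unit(x = 150, y = 150, z_top = -40,
                               z_bottom = 195, radius = 12, step = 8),
                    cortex_z = 200)
  set.seed(10)
  u <- assign_abeta(u, p, positive = TRUE)
  u$segments$abeta_positive <- TRUE   # ensure D0 positive regardless of front
  u$segments$abeta_run_start <- 0
  u$segments$abeta_run_len <- u$segments$length_um
  u <- assign_sma_loss(u, p)
  s <- structure(list(units = list(u), spots = tibble::tibble(
    spot_id = integer(), x_um = numeric(), y_um = numeric(),
    z_um = numeric(), radius_um = numeric()),
    dyshoric = tibble::tibble(unit_id = 1L,
                              seg_id = u$segments$seg_id[
                                u$segments$label == "D0"],
                              label = "D0", start_um = 30,
                              length_um = 90, r_in_um = 5, r_out_um = 20),
    params = p, seed = 91L), class = "gt_sample")
  vol <- rasterize(s)
  flags <- flag_dyshoric(vol, u, s$spots, intensity_threshold = 5000)
  expect_identical(flags, "D0")
  # no sleeve -> nothing flagged
  s2 <- s; s2$dyshoric <- s2$dyshoric[0, ]
  vol2 <- rasterize(s2)
  expect_length(flag_dyshoric(vol2, u, s$spots, 5000), 0)
  # an isolated spherical blob 15 um off the wall fails the linear test
  blob <- caa3d:::world_to_vox(rbind(c(150 + 12 + 15 + 10, 150, 100)),
                               vol2$voxel_size_um, vol2$origin_um)
  cpp_stamp_spheres(vol2$abeta, dim(vol2$abeta), blob, 10 / 2, 20000)
  expect_length(flag_dyshoric(vol2, u, s$spots, 5000), 0)
})
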