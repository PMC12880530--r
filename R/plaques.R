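#' Detect plaque spots in the amyloid channel
#'
#' Scale-matched blob detection: the channel is smoothed with a Gaussian
#' of sigma = diameter / (2 sqrt(3)) (the Laplacian-of-Gaussian scale for
#' a blob of the target diameter), the negative scale-normalized Laplacian
#' is evaluated, and its local maxima are kept if the smoothed intensity
#' at the maximum ("quality") exceeds `quality_min`, then greedily
#' non-maximum suppressed at half the spot diameter. Dyshoric sleeves are
#' elongated, not spherical, and do not produce LoG maxima of this scale.
#'
#' @param volume a [two_channel_volume].
#' @param diameter_um spot diameter in um (default 50).
#' @param quality_min minimum quality (smoothed amyloid intensity at the
#'   detected center).
#' @return tibble of spots: `x_um`, `y_um`, `z_um`, `radius_um`
#'   (= diameter/2), `quality`, `log_response`.
#' @export
detect_spots <- function(volume, diameter_um = 50, quality_min) {
  v <- volume$voxel_size_um
  if (diameter_um < 2 * v) {
    stop("spot diameter must be at least 2 voxels (", 2 * v, " um)")
  }
  a <- volume$abeta
  dims <- dim(a)
  sigma_vox <- diameter_um / (2 * sqrt(3)) / v
  sm <- cpp_gauss3d(a, as.integer(dims), sigma_vox)
  logr <- -sigma_vox^2 * array_laplacian(sm)
  cand <- cpp_local_maxima(logr, as.integer(dims), 0)
  empty <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          z_um = numeric(), radius_um = numeric(),
                          quality = numeric(), log_response = numeric())
  if (!length(cand)) return(empty)
  q <- sm[cand]
  keep <- q >= quality_min
  cand <- cand[keep]; q <- q[keep]
  if (!length(cand)) return(empty)
  idx <- arrayInd(cand, dims)
  world <- vox_to_world(idx, v, volume$origin_um)
  resp <- logr[cand]
  ord <- order(resp, decreasing = TRUE)
  sup2 <- (0.5 * diameter_um)^2
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    d2 <- rowSums((world[kept, , drop = FALSE] -
                     matrix(world[i, ], length(kept), 3, byrow = TRUE))^2)
    if (all(d2 > sup2)) kept <- c(kept, i)
  }
  tibble::tibble(x_um = world[kept, 1], y_um = world[kept, 2],
                 z_um = world[kept, 3], radius_um = diameter_um / 2,
                 quality = q[kept], log_response = resp[kept])
}

# discrete 6-neighbor Laplacian with replicated edges
array_laplacian <- function(a) {
  dims <- dim(a)
  out <- -6 * a
  shift <- function(a, axis, by) {
    idx <- lapply(dims, seq_len)
    i <- idx[[axis]] + by
    idx[[axis]] <- pmin(pmax(i, 1L), dims[axis])
    do.call(`[`, c(list(a), idx))
  }
  for (axis in 1:3) {
    out <- out + shift(a, axis, 1L) + shift(a, axis, -1L)
  }
  out
}

#' Flag dual-channel autofluorescence artifacts
#'
#' Lipofuscin-like puncta fluoresce in both channels: a spot is flagged
#' as an artifact iff the smoothed SMA intensity at its center is at
#' least `ratio_alpha` times its quality. Flagged spots are retained in
#' the table (with `is_artifact = TRUE`) but must be dropped from density
#' analyses.
#'
#' @param spots tibble from [detect_spots()].
#' @param volume the [two_channel_volume] (SMA channel is used).
#' @param diameter_um smoothing scale, matching the detection scale.
#' @param ratio_alpha SMA/quality ratio threshold (default 0.8).
#' @return `spots` with `sma_intensity` and `is_artifact` columns.
#' @export
exclude_artifacts <- function(spots, volume, diameter_um = 50,
                              ratio_alpha = 0.8) {
  if (!nrow(spots)) {
    spots$sma_intensity <- numeric(0)
    spots$is_artifact <- logical(0)
    return(spots)
  }
  v <- volume$voxel_size_um
  sigma_vox <- diameter_um / (2 * sqrt(3)) / v
  sm <- cpp_gauss3d(volume$sma, as.integer(dim(volume$sma)), sigma_vox)
  pts <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  spots$sma_intensity <- sample_voxels(sm, v, pts, volume$origin_um)
  spots$is_artifact <- spots$sma_intensity >= ratio_alpha * spots$quality
  spots
}

#' Distance from a point to a polyline
#'
#' Minimum over the polyline's line segments of the clamped-projection
#' (point-to-segment) distance.
#'
#' @param point length-3 numeric (um).
#' @param polyline n x 3 matrix, or a labeled [vascular_unit] (minimum
#'   over all its segment polylines).
#' @return distance in um.
#' @export
point_polyline_distance <- function(point, polyline) {
  if (inherits(polyline, "vascular_unit")) {
    return(min(vapply(polyline$segments$polyline,
                      function(p) point_polyline_distance(point, p),
                      numeric(1))))
  }
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  ab <- b - a
  ap <- matrix(point, nrow(a), 3, byrow = TRUE) - a
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  e <- ap - t * ab
  sqrt(min(rowSums(e^2)))
}

#' Spots within the perivascular band of one unit
#'
#' Keeps spots whose center-to-filament distance to THIS unit lies in the
#' inclusive band (default 10 to 100 um). The 10 um inner bound removes
#' on-wall deposits from the plaque count.
#'
#' @param unit a labeled [vascular_unit].
#' @param spots tibble with `x_um`, `y_um`, `z_um` (artifacts should be
#'   excluded beforehand).
#' @param band inclusive distance bounds in um, default `c(10, 100)`.
#' @return the spot subset, with `nearest_distance_um` appended.
#' @export
perivascular_spots <- function(unit, spots, band = c(10, 100)) {
  if (!nrow(spots)) {
    spots$nearest_distance_um <- numeric(0)
    return(spots)
  }
  pts <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  soup <- unit_edge_soup(list(unit))
  d <- cpp_min_dist_groups(pts, soup$a, soup$b,
                           rep(1L, length(soup$group)), 1L)[, 1]
  spots$nearest_distance_um <- d
  spots[d >= band[1] & d <= band[2], , drop = FALSE]
}

#' Restrict to cortical units for density analysis
#'
#' Drops units with any node beyond the cortex / white-matter boundary
#' (plaque density differs sharply between cortex and medulla) and units
#' flagged as excluded (no entry or perivascular artifacts).
#'
#' @param units list of [vascular_unit]s.
#' @param cortex_z boundary depth in um.
#' @return the retained sublist.
#' @export
exclude_wm_units <- function(units, cortex_z) {
  Filter(function(u) {
    is.na(u$excluded_reason) && !any(u$nodes$z > cortex_z)
  }, units)
}

#' Length-normalized perivascular plaque density
#'
#' @param unit a labeled [vascular_unit].
#' @param spots_in_band spots already filtered by [perivascular_spots()].
#' @return one-row tibble: `unit_id`, `abeta_positive`,
#'   `n_spots_in_band`, `filament_length_um`, `density_per_um`.
#' @export
plaque_density <- function(unit, spots_in_band) {
  len <- sum(unit$segments$length_um)
  tibble::tibble(unit_id = unit$unit_id,
                 abeta_positive = isTRUE(unit$abeta_positive),
                 n_spots_in_band = nrow(spots_in_band),
                 filament_length_um = len,
                 density_per_um = nrow(spots_in_band) / len)
}

#' Per-unit density table for a whole sample
#'
#' Batch driver: excludes white-matter-penetrating and flagged units,
#' computes every spot-to-unit filament distance once, applies the
#' inclusive band, and normalizes by filament length.
#'
#' @param units list of labeled, status-assigned units.
#' @param spots spot table (artifact rows are dropped if an
#'   `is_artifact` column is present).
#' @param cortex_z cortex boundary (um).
#' @param band inclusive band (um), default `c(10, 100)`.
#' @return tibble with one density record per retained unit.
#' @export
perivascular_density_table <- function(units, spots, cortex_z,
                                       band = c(10, 100)) {
  keep <- exclude_wm_units(units, cortex_z)
  if (!length(keep)) {
    return(tibble::tibble(unit_id = integer(), abeta_positive = logical(),
                          n_spots_in_band = integer(),
                          filament_length_um = numeric(),
                          density_per_um = numeric()))
  }
  if ("is_artifact" %in% names(spots)) {
    spots <- spots[!spots$is_artifact, , drop = FALSE]
  }
  nu <- length(keep)
  counts <- rep(0L, nu)
  if (nrow(spots)) {
    soup <- unit_edge_soup(keep)
    d <- cpp_min_dist_groups(as.matrix(spots[, c("x_um", "y_um", "z_um")]),
                             soup$a, soup$b, soup$group, nu)
    counts <- colSums(d >= band[1] & d <= band[2])
  }
  do.call(rbind, lapply(seq_len(nu), function(i) {
    u <- keep[[i]]
    len <- sum(u$segments$length_um)
    tibble::tibble(unit_id = u$unit_id,
                   abeta_positive = isTRUE(u$abeta_positive),
                   n_spots_in_band = as.integer(counts[i]),
                   filament_length_um = len,
                   density_per_um = counts[i] / len)
  }))
}

#' Flag dyshoric change on a unit from the image
#'
#' A segment is flagged iff perivascular amyloid in an annulus just
#' outside the wall — excluding voxels explained by retained plaque spots
#' — covers a contiguous longitudinal run of at least `length_min_um`
#' with at least `coverage_min` of the circumferential samples above
#' threshold. Isolated spherical blobs fail the linear-extent test;
#' on-wall deposits lie inside the annulus inner bound.
#'
#' @param volume a [two_channel_volume].
#' @param unit a labeled, amyloid-positive cortical [vascular_unit].
#' @param spots retained (non-artifact) spots; samples within a spot's
#'   radius of its center are discounted.
#' @param intensity_threshold deposit threshold.
#' @param annulus radial offsets (um) beyond the wall, default
#'   `c(5, 20)` matching the generated sleeves.
#' @param coverage_min minimum circumferential coverage per step
#'   (default 0.5).
#' @param length_min_um minimum linear extent (default 50).
#' @param step_um centerline step (default 2).
#' @return character vector of flagged segment labels (unique).
#' @export
flag_dyshoric <- function(volume, unit, spots, intensity_threshold,
                          annulus = c(5, 20), coverage_min = 0.5,
                          length_min_um = 50, step_um = 2) {
  seg <- unit$segments
  v <- volume$voxel_size_um
  arr <- volume$abeta
  spot_pts <- if (nrow(spots)) {
    as.matrix(spots[, c("x_um", "y_um", "z_um")])
  } else {
    NULL
  }
  flagged <- character(0)
  n_angles <- 12
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  # inner offset keeps a voxel-rounding margin beyond the wall deposit
  offs <- seq(annulus[1] + 4, annulus[2] - 1, length.out = 3)
  for (j in which(label_rank(seg$label) >= 1)) {
    rs <- resample_polyline(seg$polyline[[j]], step_um, seg$radii[[j]])
    basis <- perp_basis(rs$tangents)
    cover <- matrix(FALSE, nrow(rs$points), n_angles)
    for (ai in seq_along(angles)) {
      dirv <- cos(angles[ai]) * basis$u + sin(angles[ai]) * basis$v
      for (o in offs) {
        p <- rs$points + (rs$radius + o) * dirv
        hit <- sample_voxels(arr, v, p, volume$origin_um) > intensity_threshold
        if (!is.null(spot_pts)) {
          for (k in seq_len(nrow(spot_pts))) {
            d2 <- rowSums((p - matrix(spot_pts[k, ], nrow(p), 3,
                                      byrow = TRUE))^2)
            hit[d2 <= spots$radius_um[k]^2] <- FALSE
          }
        }
        cover[, ai] <- cover[, ai] | hit
      }
    }
    frac <- rowMeans(cover)
    if (longest_run_um(frac >= coverage_min, step_um) >= length_min_um) {
      flagged <- c(flagged, seg$label[j])
    }
  }
  unique(flagged)
}
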