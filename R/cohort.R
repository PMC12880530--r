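#' Simulate a ground-truth CAA cohort sample
#'
#' Generates `n_units` vascular units on a jittered entry grid, labels
#' their depths, assigns ground-truth amyloid deposition (surface-to-depth
#' front model), smooth-muscle loss, parenchymal plaque spots (Poisson
#' process thinned near amyloid-positive vessels) and dyshoric sleeves.
#' All randomness flows from `params$seed`, so identical parameters give
#' an identical sample.
#'
#' @param params a [cohort_params].
#' @return an object of class `gt_sample`: list with `units` (labeled
#'   [vascular_unit]s with truth statuses), `spots` (tibble of plaque
#'   ground truth), `dyshoric` (tibble of sleeve descriptors), `params`,
#'   `seed`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_units
  sx <- params$slab_dims_um[1]; sy <- params$slab_dims_um[2]

  # jittered grid of entry points emulating the spacing of penetrating
  # arteries over the surface
  g <- ceiling(sqrt(n))
  gx <- (rep(seq_len(g), g)[seq_len(n)] - 0.5) / g
  gy <- (rep(seq_len(g), each = g)[seq_len(n)] - 0.5) / g
  jit <- 0.25 / g
  ex <- pmin(pmax(gx + stats::runif(n, -jit, jit), 0.02), 0.98) * sx
  ey <- pmin(pmax(gy + stats::runif(n, -jit, jit), 0.02), 0.98) * sy

  pos_flag <- stats::runif(n) < params$p_unit_abeta
  wm_flag <- stats::runif(n) < params$p_penetrate_wm
  med <- ifelse(pos_flag, params$diameter_root_median_pos_um,
                params$diameter_root_median_neg_um)
  diam <- stats::rlnorm(n, log(med), params$diameter_sdlog)

  units <- vector("list", n)
  for (i in seq_len(n)) {
    u <- generate_unit_geometry(params, unit_id = i,
                                entry_xy = c(ex[i], ey[i]),
                                root_diameter_um = diam[i],
                                penetrates_wm = wm_flag[i])
    u <- label_depths(u, surface_z = 0, bif_radius_factor = 2,
                      cortex_z = params$cortex_thickness_um)
    u <- assign_abeta(u, params, positive = pos_flag[i])
    u <- assign_sma_loss(u, params)
    units[[i]] <- u
  }
  spots <- sample_plaques(units, params)
  dysh <- place_dyshoric(units, params)
  structure(list(units = units, spots = spots, dyshoric = dysh,
                 params = params, seed = params$seed),
            class = "gt_sample")
}

#' @export
print.gt_sample <- function(x, ...) {
  npos <- sum(vapply(x$units, function(u) isTRUE(u$abeta_positive),
                     logical(1)))
  cat("<gt_sample>", length(x$units), "units (", npos, "amyloid-positive ),",
      nrow(x$spots), "plaque spots,", nrow(x$dyshoric),
      "dyshoric sleeves, seed", x$seed, "\n")
  invisible(x)
}

#' Sample ground-truth parenchymal plaque spots
#'
#' Homogeneous Poisson candidates with intensity `plaque_lambda0` per um^3
#' of cortex; candidates within 100 um of any amyloid-positive unit's
#' skeleton are retained with probability `plaque_thinning_theta`, all
#' others with probability 1. This thinning emulates the observed plaque
#' rarefaction around amyloid-laden arteries. Radii are lognormal with
#' parameters `plaque_radius_um`.
#'
#' @param units list of labeled, status-assigned [vascular_unit]s.
#' @param params a [cohort_params].
#' @return tibble with columns `spot_id`, `x_um`, `y_um`, `z_um`,
#'   `radius_um` (truth spots all lie in cortex).
#' @export
sample_plaques <- function(units, params) {
  sx <- params$slab_dims_um[1]; sy <- params$slab_dims_um[2]
  cz <- params$cortex_thickness_um
  vol <- sx * sy * cz
  n <- stats::rpois(1, params$plaque_lambda0 * vol)
  empty <- tibble::tibble(spot_id = integer(), x_um = numeric(),
                          y_um = numeric(), z_um = numeric(),
                          radius_um = numeric())
  if (n == 0) return(empty)
  pts <- cbind(stats::runif(n, 0, sx), stats::runif(n, 0, sy),
               stats::runif(n, 0, cz))
  radius <- stats::rlnorm(n, params$plaque_radius_um["meanlog"],
                          params$plaque_radius_um["sdlog"])
  keep <- rep(TRUE, n)
  live <- Filter(function(u) is.na(u$excluded_reason), units)
  soup <- unit_edge_soup(live)
  if (!is.null(soup)) {
    d <- cpp_min_dist_groups(pts, soup$a, soup$b, soup$group,
                             length(live))
    # hard-core clearance: plaques are parenchymal, never intramural.
    # The clearance is uniform across units (cap radius + wall band +
    # sampling margin) so that it cannot act as a diameter-linked
    # covariate between amyloid-positive and negative units
    clearance <- radius + params$diameter_cap_um / 2 + 13
    keep <- keep & apply(d, 1, min) >= clearance
    pos <- vapply(live, function(u) isTRUE(u$abeta_positive), logical(1))
    if (any(pos)) {
      near <- apply(d[, pos, drop = FALSE], 1, min) <= 100
      thin <- near & stats::runif(n) >= params$plaque_thinning_theta
      keep <- keep & !thin
    }
  }
  pts <- pts[keep, , drop = FALSE]
  m <- nrow(pts)
  if (m == 0) return(empty)
  tibble::tibble(
    spot_id = seq_len(m),
    x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
    radius_um = radius[keep])
}

#' Place ground-truth dyshoric sleeves
#'
#' Each amyloid-positive cortical unit develops dyshoric change with
#' probability `p_dyshoric_unit`. The affected segment is D0 with
#' probability `dyshoric_d0_share`, otherwise uniform among the unit's
#' other amyloid-positive cortical segments (falling back to D0 when no
#' alternative exists). The sleeve is described by its segment, a
#' longitudinal extent, and an annulus 5-20 um outside the vessel wall.
#'
#' @inheritParams sample_plaques
#' @return tibble with columns `unit_id`, `seg_id`, `label`, `start_um`,
#'   `length_um`, `r_in_um`, `r_out_um`.
#' @export
place_dyshoric <- function(units, params) {
  rows <- list()
  for (u in units) {
    if (!isTRUE(u$abeta_positive) || !is.na(u$excluded_reason) ||
        isTRUE(u$penetrates_wm) || is.null(u$segments)) next
    seg <- u$segments
    rank <- label_rank(seg$label)
    cort <- seg$abeta_positive & rank >= 1 & !seg$in_white_matter
    d0 <- which(cort & seg$label == "D0")
    # dyshoric change accompanies heavy superficial deposition: only
    # units with an amyloid-positive D0 segment are eligible
    if (!length(d0)) next
    if (stats::runif(1) >= params$p_dyshoric_unit) next
    alt <- which(cort & seg$label != "D0")
    pick_d0 <- stats::runif(1) < params$dyshoric_d0_share
    j <- if (pick_d0 && length(d0)) d0[1]
         else if (length(alt)) alt[sample.int(length(alt), 1)]
         else if (length(d0)) d0[1]
         else which(cort)[1]
    len <- min(seg$length_um[j],
               stats::rlnorm(1, params$dyshoric_len_um["meanlog"],
                             params$dyshoric_len_um["sdlog"]))
    rows[[length(rows) + 1]] <- tibble::tibble(
      unit_id = u$unit_id, seg_id = seg$seg_id[j], label = seg$label[j],
      start_um = stats::runif(1, 0, seg$length_um[j] - len),
      length_um = len, r_in_um = 5, r_out_um = 20)
  }
  if (!length(rows)) {
    return(tibble::tibble(unit_id = integer(), seg_id = integer(),
                          label = character(), start_um = numeric(),
                          length_um = numeric(), r_in_um = numeric(),
                          r_out_um = numeric()))
  }
  do.call(rbind, rows)
}

#' Attribute dyshoric sleeves to segments from geometry
#'
#' Truth-path counterpart of the image-based [flag_dyshoric()]: each
#' sleeve is represented by a point at its longitudinal midpoint, offset
#' radially into the middle of its annulus, and attributed to the nearest
#' cortical segment of its unit by point-to-polyline distance. Used to
#' recover the segment-placement distribution (e.g. the D0 share) without
#' rasterizing.
#'
#' @param units list of labeled units.
#' @param dyshoric sleeve table from [place_dyshoric()].
#' @return `dyshoric` with an `attributed_label` column appended.
#' @export
attribute_dyshoric <- function(units, dyshoric) {
  by_id <- stats::setNames(units,
                           vapply(units, function(u) as.character(u$unit_id),
                                  character(1)))
  lab <- character(nrow(dyshoric))
  for (i in seq_len(nrow(dyshoric))) {
    u <- by_id[[as.character(dyshoric$unit_id[i])]]
    seg <- u$segments
    j <- match(dyshoric$seg_id[i], seg$seg_id)
    # three probe points along the sleeve, each offset into the annulus;
    # the segment winning the majority of probes is the attribution
    probes <- dyshoric$start_um[i] +
      dyshoric$length_um[i] * c(0.25, 0.5, 0.75)
    at <- polyline_at(seg$polyline[[j]], probes, seg$radii[[j]])
    basis <- perp_basis(at$tangents)
    cand <- which(label_rank(seg$label) >= 1)
    votes <- character(0)
    for (q in seq_along(probes)) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- at$radius[q] + (dyshoric$r_in_um[i] + dyshoric$r_out_um[i]) / 2
      p <- at$points[q, ] + off * (cos(ang) * basis$u[q, ] +
                                     sin(ang) * basis$v[q, ])
      d <- vapply(cand, function(k)
        point_polyline_distance(p, seg$polyline[[k]]), numeric(1))
      votes <- c(votes, seg$label[cand[which.min(d)]])
    }
    tv <- sort(table(votes), decreasing = TRUE)
    lab[i] <- names(tv)[1]
  }
  dyshoric$attributed_label <- lab
  dyshoric
}

#' Write a ground-truth sample to disk
#'
#' Emits one SWC file per unit (`unit_<id>.swc`), truth tables
#' (`units.csv`, `segments.csv`, `spots.csv`, `dyshoric.csv`) and the
#' parameters echoed as YAML (`params.yaml`).
#'
#' @param sample a `gt_sample`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (u in sample$units) {
    write_swc(u, file.path(dir, sprintf("unit_%04d.swc", u$unit_id)))
  }
  units_df <- do.call(rbind, lapply(sample$units, function(u) {
    data.frame(unit_id = u$unit_id,
               abeta_positive = isTRUE(u$abeta_positive),
               sma_loss = isTRUE(u$sma_loss),
               front_label = u$front_label,
               is_skip = isTRUE(u$is_skip),
               is_wm_confined = isTRUE(u$is_wm_confined),
               penetrates_wm = isTRUE(u$penetrates_wm),
               excluded_reason = u$excluded_reason,
               entry_x = u$entry_point[1], entry_y = u$entry_point[2])
  }))
  utils::write.csv(units_df, file.path(dir, "units.csv"), row.names = FALSE)
  utils::write.csv(segments_table(sample$units),
                   file.path(dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(sample$spots, file.path(dir, "spots.csv"),
                   row.names = FALSE)
  utils::write.csv(sample$dyshoric, file.path(dir, "dyshoric.csv"),
                   row.names = FALSE)
  p <- unclass(sample$params)
  p$front_reach_probs <- as.list(p$front_reach_probs)
  yaml::write_yaml(p, file.path(dir, "params.yaml"))
  invisible(dir)
}
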