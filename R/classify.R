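#' Classify a segment's amyloid status from the image
#'
#' Samples the amyloid channel in an annulus around the vessel wall
#' (radial offsets `wall_band` beyond the local radius, 8 circumferential
#' directions, 3 radial depths) at centerline steps of at most 2 um. The
#' per-step intensity is the maximum over the annulus samples; the
#' segment is positive iff some contiguous above-threshold run is at
#' least `run_min_um` long. The fraction of steps above threshold is
#' recorded as coverage.
#'
#' @param volume a [two_channel_volume] or bare amyloid array.
#' @param polyline,radii segment centerline (n x 3, um) and radii (um).
#' @param wall_band radial offsets (um) beyond the wall defining the
#'   sampled annulus, default `c(0, 6)`.
#' @param intensity_threshold intensity above which a sample counts as
#'   deposit.
#' @param run_min_um minimum contiguous positive run (default 10).
#' @param voxel voxel size (um) when `volume` is a bare array.
#' @param step_um centerline step (default 2).
#' @param competitors optional edge soup (`a`, `b`, `r`) of other tube
#'   walls; annulus samples closer (radius-normalized, 4 um blur margin)
#'   to a competing wall than to this segment's wall are discounted, so
#'   wall signal is attributed to the nearest traced filament.
#'   [classify_units()] builds this from the unit's non-adjacent
#'   segments plus nearby foreign units.
#' @return list with `positive`, `coverage`, `longest_run_um`.
#' @export
classify_segment_abeta <- function(volume, polyline, radii,
                                   intensity_threshold,
                                   wall_band = c(0, 6), run_min_um = 10,
                                   voxel = NULL, step_um = 2,
                                   competitors = NULL) {
  a <- channel_array(volume, "abeta"); voxel <- a$voxel
  prof <- annulus_profile(a$arr, voxel, polyline, radii, wall_band, step_um,
                          origin = a$origin, competitors = competitors)
  above <- prof$intensity > intensity_threshold
  run <- longest_run_um(above, step_um)
  list(positive = run >= run_min_um,
       coverage = mean(above),
       longest_run_um = run)
}

#' Classify a segment's smooth-muscle status from the image
#'
#' Samples the SMA channel along the centerline; the vessel counts as
#' traceable (SMA present) iff its longest contiguous below-threshold run
#' is at most `gap_max_um` (inclusive boundary: a gap of exactly
#' `gap_max_um` still counts as present).
#'
#' @inheritParams classify_segment_abeta
#' @param gap_max_um maximum tolerated SMA gap (default 20).
#' @return list with `present`, `longest_gap_um`.
#' @export
classify_segment_sma <- function(volume, polyline, radii,
                                 intensity_threshold, gap_max_um = 20,
                                 voxel = NULL, step_um = 2) {
  a <- channel_array(volume, "sma"); voxel <- a$voxel
  rs <- resample_polyline(polyline, step_um, radii)
  val <- sample_voxels(a$arr, voxel, rs$points, a$origin)
  gap <- longest_run_um(val < intensity_threshold, step_um)
  list(present = gap <= gap_max_um, longest_gap_um = gap)
}

channel_array <- function(volume, which) {
  if (inherits(volume, "two_channel_volume")) {
    list(arr = volume[[which]], voxel = volume$voxel_size_um,
         origin = volume$origin_um)
  } else {
    stop("pass a two_channel_volume (bare arrays need explicit wrapping)")
  }
}

sample_voxels <- function(arr, voxel, points, origin = c(0, 0, 0),
                          clamp = TRUE) {
  dims <- dim(arr)
  idx <- round(world_to_vox(points, voxel, origin)) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= dims[3]
  if (!clamp && !all(inside)) stop("segment outside volume bounds")
  for (d in 1:3) idx[, d] <- pmin(pmax(idx[, d], 1), dims[d])
  arr[idx]
}

# per-step max intensity over an annulus around the centerline; when
# `competitors` (an edge soup of the other tube walls, from
# `wall_edge_soup()`) is given, samples lying closer to a competing wall
# than to this segment's wall are discounted, attributing wall signal to
# the nearest traced filament
annulus_profile <- function(arr, voxel, polyline, radii, band, step_um,
                            n_angles = 8, n_radial = 3,
                            origin = c(0, 0, 0), competitors = NULL) {
  rs <- resample_polyline(polyline, step_um, radii)
  # centerline must lie inside the volume
  sample_voxels(arr, voxel, rs$points, origin, clamp = FALSE)
  basis <- perp_basis(rs$tangents)
  offs <- seq(band[1] + 0.5, band[2] - 0.5, length.out = n_radial)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  n_steps <- nrow(rs$points)
  pts <- matrix(0, n_steps * n_angles * n_radial, 3)
  row <- 0L
  for (ang in angles) {
    dirv <- cos(ang) * basis$u + sin(ang) * basis$v
    for (o in offs) {
      pts[row + seq_len(n_steps), ] <- rs$points + (rs$radius + o) * dirv
      row <- row + n_steps
    }
  }
  val <- sample_voxels(arr, voxel, pts, origin)
  if (!is.null(competitors) && nrow(competitors$a)) {
    own <- polyline_edges(polyline, radii)
    own_nd <- cpp_min_wall_dist(pts, own$a, own$b, own$r)
    comp_nd <- cpp_min_wall_dist(pts, competitors$a, competitors$b,
                                 competitors$r)
    # the margin accounts for PSF blur and voxel rounding carrying a
    # competing wall's signal slightly past the attribution bisector
    val[comp_nd < own_nd + 4] <- -Inf
  }
  best <- rep(-Inf, n_steps)
  for (blk in seq_len(n_angles * n_radial)) {
    best <- pmax(best, val[(blk - 1) * n_steps + seq_len(n_steps)])
  }
  list(intensity = best, s = rs$s)
}

polyline_edges <- function(polyline, radii) {
  n <- nrow(polyline)
  list(a = polyline[-n, , drop = FALSE], b = polyline[-1, , drop = FALSE],
       r = (radii[-n] + radii[-1]) / 2)
}

# edge soup (with radii) of a unit's segments, excluding a segment, its
# continuation neighbors (parent, children) and its siblings: those meet
# it at a junction and share its deposition status, so they are not
# competing attributions for wall signal
wall_edge_soup <- function(segments, skip_seg) {
  par <- segments$parent_seg[match(skip_seg, segments$seg_id)]
  adjacent <- c(skip_seg, par,
                segments$seg_id[which(segments$parent_seg %in% skip_seg)],
                if (!is.na(par))
                  segments$seg_id[which(segments$parent_seg %in% par)])
  keep <- which(!(segments$seg_id %in% adjacent))
  if (!length(keep)) {
    return(list(a = matrix(0, 0, 3), b = matrix(0, 0, 3), r = numeric(0)))
  }
  es <- lapply(keep, function(k)
    polyline_edges(segments$polyline[[k]], segments$radii[[k]]))
  list(a = do.call(rbind, lapply(es, `[[`, "a")),
       b = do.call(rbind, lapply(es, `[[`, "b")),
       r = unlist(lapply(es, `[[`, "r")))
}

# merge two edge soups
merge_soup <- function(s1, s2) {
  if (is.null(s2) || !nrow(s2$a)) return(s1)
  list(a = rbind(s1$a, s2$a), b = rbind(s1$b, s2$b), r = c(s1$r, s2$r))
}

# per-unit soup of OTHER units' walls within reach of this unit's
# bounding box; foreign vessels compete for wall-signal attribution just
# like the unit's own distant branches
foreign_wall_soup <- function(units, reach = 50) {
  boxes <- lapply(units, function(u) {
    pts <- do.call(rbind, u$segments$polyline)
    rbind(apply(pts, 2, min), apply(pts, 2, max))
  })
  lapply(seq_along(units), function(i) {
    lo <- boxes[[i]][1, ] - reach; hi <- boxes[[i]][2, ] + reach
    es <- list()
    for (k in seq_along(units)) {
      if (k == i) next
      if (any(boxes[[k]][1, ] > hi) || any(boxes[[k]][2, ] < lo)) next
      sk <- units[[k]]$segments
      for (j in seq_len(nrow(sk))) {
        es[[length(es) + 1]] <- polyline_edges(sk$polyline[[j]],
                                               sk$radii[[j]])
      }
    }
    if (!length(es)) return(NULL)
    list(a = do.call(rbind, lapply(es, `[[`, "a")),
         b = do.call(rbind, lapply(es, `[[`, "b")),
         r = unlist(lapply(es, `[[`, "r")))
  })
}

longest_run_um <- function(flag, step_um) {
  if (!any(flag)) return(0)
  r <- rle(flag)
  max(r$lengths[r$values]) * step_um
}

#' Unit-level amyloid status
#'
#' A vascular unit is amyloid-positive iff any of its segments (including
#' the LMA) is positive.
#'
#' @param x a status-assigned [vascular_unit] or a logical vector /
#'   data.frame with an `abeta_positive` column for one unit's segments.
#' @return logical.
#' @export
unit_abeta_status <- function(x) {
  if (inherits(x, "vascular_unit")) x <- x$segments
  if (is.data.frame(x)) x <- x$abeta_positive
  any(as.logical(x))
}

load_class <- function(fraction) {
  if (fraction < 0.40) "low" else if (fraction <= 0.60) "moderate"
  else "high"
}

#' Vascular amyloid load of one sample
#'
#' The load is the fraction of amyloid-positive vascular units among all
#' units of a sample, classed low (< 40%), moderate (40 to 60%, closed
#' interval) or high (> 60%). Per-segment load rates are computed among
#' positive units: for label L, the fraction of positive units possessing
#' L that carry an amyloid-positive segment labeled L (set
#' `denominator = "all_positive"` to divide by all positive units
#' instead).
#'
#' @param x a list of status-assigned [vascular_unit]s, or a data.frame
#'   with columns `unit_id`, `label`, `abeta_positive` (one row per
#'   segment piece).
#' @param denominator `"possessing"` (default) or `"all_positive"`.
#' @return an object of class `load_summary`: list with `n_units`,
#'   `n_positive`, `load_fraction`, `load_class` and `per_segment_rates`
#'   (tibble `label`, `n_possessing`, `n_with_positive`, `rate`).
#' @export
vascular_load <- function(x, denominator = c("possessing", "all_positive")) {
  denominator <- match.arg(denominator)
  if (is.list(x) && !is.data.frame(x)) {
    x <- Filter(function(u) is.na(u$excluded_reason), x)
    if (!length(x)) stop("no units to summarize")
    st <- segments_table(x)
  } else {
    st <- x
  }
  if (!nrow(st)) stop("empty sample")
  upos <- tapply(st$abeta_positive, st$unit_id, any)
  n_units <- length(upos)
  n_pos <- sum(upos)
  frac <- n_pos / n_units
  pos_ids <- names(upos)[upos]
  stp <- st[as.character(st$unit_id) %in% pos_ids, , drop = FALSE]
  labs <- intersect(label_levels(), unique(stp$label))
  rates <- lapply(labs, function(L) {
    has <- tapply(stp$label == L, stp$unit_id, any)
    hit <- tapply(stp$label == L & stp$abeta_positive, stp$unit_id, any)
    denom <- if (denominator == "possessing") sum(has) else length(has)
    tibble::tibble(label = L, n_possessing = sum(has),
                   n_with_positive = sum(hit),
                   rate = if (denom > 0) sum(hit) / denom else NA_real_)
  })
  structure(list(n_units = n_units, n_positive = n_pos,
                 load_fraction = frac, load_class = load_class(frac),
                 per_segment_rates = do.call(rbind, rates)),
            class = "load_summary")
}

#' @export
print.load_summary <- function(x, ...) {
  cat(sprintf("<load_summary> %d/%d positive (%.1f%%) -> %s\n",
              x$n_positive, x$n_units, 100 * x$load_fraction,
              x$load_class))
  print(x$per_segment_rates)
  invisible(x)
}

#' Most superficial segment with smooth-muscle loss
#'
#' @param unit a status-assigned [vascular_unit] (or its segment
#'   data.frame with `label` and `sma_present`).
#' @return the most superficial (minimum-rank) label among SMA-lost
#'   segments, or `NA_character_` when the unit has no loss.
#' @export
most_superficial_sma_loss <- function(unit) {
  seg <- if (inherits(unit, "vascular_unit")) unit$segments else unit
  lost <- which(!seg$sma_present)
  if (!length(lost)) return(NA_character_)
  seg$label[lost[which.min(label_rank(seg$label[lost]))]]
}

#' Detect the skip deposition pattern
#'
#' A unit shows a skip pattern iff some amyloid-positive segment has, on
#' its path back to the entry point, at least one amyloid-negative
#' segment of strictly more superficial label (the LMA is excluded from
#' the path requirement).
#'
#' @param unit a status-assigned [vascular_unit] (or a segment data.frame
#'   with `seg_id`, `parent_seg`, `label`, `abeta_positive`).
#' @return logical.
#' @export
detect_skip_pattern <- function(unit) {
  seg <- if (inherits(unit, "vascular_unit")) unit$segments else unit
  rank <- label_rank(seg$label)
  parent <- match(seg$parent_seg, seg$seg_id)
  for (i in which(seg$abeta_positive & seg$label != "LMA")) {
    a <- parent[i]
    while (!is.na(a)) {
      if (seg$label[a] != "LMA" && !seg$abeta_positive[a] &&
          rank[a] < rank[i] - 1e-9) {
        return(TRUE)
      }
      a <- parent[a]
    }
  }
  FALSE
}

#' Classify all units of a sample against a two-channel volume
#'
#' Runs [classify_segment_abeta()] and [classify_segment_sma()] over every
#' segment of every (non-excluded) unit and rolls the results up into a
#' status table and a [vascular_load()] summary.
#'
#' @param volume a [two_channel_volume].
#' @param units list of labeled [vascular_unit]s.
#' @param intensity_threshold shared deposit/SMA intensity threshold.
#' @param wall_band,run_min_um,gap_max_um see the segment classifiers.
#' @return list with `status` (tibble: `unit_id`, `seg_id`, `label`,
#'   `abeta_positive`, `abeta_coverage`, `sma_present`) and `load` (a
#'   `load_summary`).
#' @export
classify_units <- function(volume, units, intensity_threshold,
                           wall_band = c(0, 6), run_min_um = 10,
                           gap_max_um = 20) {
  rows <- list()
  live <- Filter(function(u) is.na(u$excluded_reason) &&
                   !is.null(u$segments), units)
  foreign <- foreign_wall_soup(live)
  for (i in seq_along(live)) {
    u <- live[[i]]
    seg <- u$segments
    for (j in seq_len(nrow(seg))) {
      comp <- merge_soup(wall_edge_soup(seg, seg$seg_id[j]),
                         foreign[[i]])
      ab <- classify_segment_abeta(volume, seg$polyline[[j]],
                                   seg$radii[[j]], intensity_threshold,
                                   wall_band, run_min_um,
                                   competitors = comp)
      sm <- classify_segment_sma(volume, seg$polyline[[j]], seg$radii[[j]],
                                 intensity_threshold, gap_max_um)
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit_id = u$unit_id, seg_id = seg$seg_id[j], label = seg$label[j],
        abeta_positive = ab$positive, abeta_coverage = ab$coverage,
        sma_present = if (ab$positive) sm$present else TRUE)
    }
  }
  status <- do.call(rbind, rows)
  list(status = status, load = vascular_load(status))
}
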