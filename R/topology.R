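#' Locate the parenchymal entry point of a vascular unit
#'
#' The entry point is the linear interpolation of the first
#' root-to-descendant edge that crosses the surface plane. Units that
#' never cross the plane (e.g. fully leptomeningeal fragments) cannot be
#' anchored to the cortex and are excluded, as is standard when a unit's
#' penetration position cannot be confirmed from the surface.
#'
#' @param unit a [vascular_unit].
#' @param surface_z surface plane height in um (default 0).
#' @return a list with `point` (length-3 numeric), `radius`, `parent_row`,
#'   `child_row` and `t` (interpolation parameter), or `NULL` when the
#'   unit has no crossing (the caller should flag reason `"no-entry"`).
#' @export
find_entry_point <- function(unit, surface_z = 0) {
  n <- unit$nodes
  ch <- children_index(n)
  root <- which(n$parent == -1L)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c in rev(ch[[v]])) {
      zp <- n$z[v] - surface_z; zc <- n$z[c] - surface_z
      if (zp <= 0 && zc > 0) {
        t <- if (zc == zp) 0 else -zp / (zc - zp)
        p <- c(n$x[v], n$y[v], n$z[v])
        q <- c(n$x[c], n$y[c], n$z[c])
        return(list(point = p + t * (q - p),
                    radius = n$radius[v] + t * (n$radius[c] - n$radius[v]),
                    parent_row = v, child_row = c, t = t))
      }
      stack <- c(stack, c)
    }
  }
  NULL
}

#' Label the segments of a vascular unit by branching depth
#'
#' Splits the skeleton at the parenchymal entry point and at every
#' bifurcation: the portion above the entry is `LMA`; below, a depth
#' counter starts at 0 and increments at each bifurcation node (both
#' children of a branch get depth d+1; trifurcations count as a single
#' bifurcation event). The arc within `bif_radius_factor` times the local
#' radius of a bifurcation node between depths d and d+1 is carved out as
#' the bifurcation segment `Dd-Dd+1`. Depths beyond 6 are pooled as
#' `DEEPER`. Every edge receives exactly one label, so labeled segment
#' lengths below the entry partition the intraparenchymal skeleton length.
#'
#' @inheritParams find_entry_point
#' @param bif_radius_factor bifurcation-zone half-extent, in units of the
#'   branch-node radius (default 2).
#' @param cortex_z depth (um) of the cortex / white-matter boundary used
#'   to set the per-segment `in_white_matter` flag and the unit's
#'   `penetrates_wm` flag; `Inf` disables the distinction.
#' @return the unit with `$segments` set to a tibble (one row per segment
#'   piece: `unit_id`, `seg_id`, `label`, `parent_seg`, `length_um`,
#'   `mean_radius_um`, `n_points`, `in_white_matter`, plus `polyline` and
#'   `radii` list-columns), `$entry_point` set, and exclusion flagged when
#'   no entry exists.
#' @export
label_depths <- function(unit, surface_z = 0, bif_radius_factor = 2,
                         cortex_z = Inf) {
  ep <- find_entry_point(unit, surface_z)
  if (is.null(ep)) {
    unit$excluded_reason <- "no-entry"
    unit$segments <- NULL
    return(unit)
  }
  n <- unit$nodes
  # insert a virtual node at the entry point, splitting the crossing edge
  eid <- max(n$id) + 1L
  n <- rbind(n, data.frame(id = eid, x = ep$point[1], y = ep$point[2],
                           z = ep$point[3], radius = ep$radius,
                           parent = n$id[ep$parent_row]))
  n$parent[ep$child_row] <- eid
  entry_row <- nrow(n)

  ch <- children_index(n)
  root <- which(n$parent == -1L)
  prow <- match(n$parent, n$id)
  elen <- sqrt((n$x - n$x[prow])^2 + (n$y - n$y[prow])^2 +
                 (n$z - n$z[prow])^2)   # edge length to parent (NA at root)

  # below-entry membership
  below <- logical(nrow(n)); below[entry_row] <- TRUE
  ord <- integer(0); stack <- root
  while (length(stack)) {            # preorder
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    if (v != root && !below[v]) below[v] <- below[prow[v]]
    if (v == entry_row) below[v] <- TRUE
    stack <- c(stack, rev(ch[[v]]))
  }
  is_bif <- vapply(seq_len(nrow(n)),
                   function(v) below[v] && length(ch[[v]]) >= 2, logical(1))

  # depth, distance to previous bifurcation (forward pass in preorder)
  depth <- rep(NA_integer_, nrow(n)); depth[entry_row] <- 0L
  d_prev <- rep(Inf, nrow(n)); r_prev <- rep(NA_real_, nrow(n))
  for (v in ord) {
    if (!below[v] || v == entry_row) next
    p <- prow[v]
    if (!below[p]) { depth[v] <- 0L; next }      # shouldn't occur
    if (is_bif[p]) {
      depth[v] <- depth[p] + 1L
      d_prev[v] <- elen[v]
      r_prev[v] <- n$radius[p]
    } else {
      depth[v] <- depth[p]
      d_prev[v] <- d_prev[p] + elen[v]
      r_prev[v] <- r_prev[p]
    }
  }
  # distance to next bifurcation (reverse pass)
  d_next <- rep(Inf, nrow(n)); r_next <- rep(NA_real_, nrow(n))
  for (v in rev(ord)) {
    if (!below[v]) next
    if (is_bif[v]) { d_next[v] <- 0; r_next[v] <- n$radius[v]; next }
    kids <- ch[[v]]
    if (length(kids) == 1) {
      d_next[v] <- d_next[kids] + elen[kids]
      r_next[v] <- r_next[kids]
    }
  }

  f <- bif_radius_factor
  edge_label <- rep(NA_character_, nrow(n))   # label of edge (parent->v)
  for (v in ord) {
    if (v == root) next
    # the edge ending at the entry node lies above the plane
    if (!below[v] || v == entry_row) { edge_label[v] <- "LMA"; next }
    d <- depth[v]
    half <- elen[v] / 2
    up <- d_prev[v] - half      # midpoint to previous bif (below entry)
    dn <- d_next[v] + half      # midpoint to next bif
    in_up <- d > 0 && is.finite(up) && up <= f * r_prev[v]
    in_dn <- is.finite(dn) && dn <= f * r_next[v]
    edge_label[v] <-
      if (in_up && (!in_dn || up <= dn)) bifurcation_label(d - 1)
      else if (in_dn) bifurcation_label(d)
      else depth_label(d)
  }

  # group contiguous same-label edges into segment pieces
  seg_of_node <- rep(NA_integer_, nrow(n))
  pieces <- list()
  new_piece <- function(label, parent_seg, start_row) {
    pieces[[length(pieces) + 1]] <<- list(
      label = label, parent_seg = parent_seg,
      rows = start_row)           # polyline starts at the upstream node
    length(pieces)
  }
  for (v in ord) {
    if (v == root) next
    p <- prow[v]
    psig <- seg_of_node[p]
    split_here <- is.na(psig) ||
      pieces[[psig]]$label != edge_label[v] ||
      is_bif[p] || p == entry_row || length(ch[[p]]) >= 2
    if (split_here) {
      sid <- new_piece(edge_label[v], if (is.na(psig)) NA_integer_ else psig, p)
    } else {
      sid <- psig
    }
    pieces[[sid]]$rows <- c(pieces[[sid]]$rows, v)
    seg_of_node[v] <- sid
  }

  polys <- lapply(pieces, function(pc)
    unname(as.matrix(n[pc$rows, c("x", "y", "z")])))
  radii <- lapply(pieces, function(pc) n$radius[pc$rows])
  seg <- tibble::tibble(
    unit_id = unit$unit_id,
    seg_id = seq_along(pieces),
    label = vapply(pieces, `[[`, character(1), "label"),
    parent_seg = vapply(pieces, `[[`, integer(1), "parent_seg"),
    length_um = vapply(polys, segment_length, numeric(1)),
    mean_radius_um = vapply(radii, mean, numeric(1)),
    n_points = vapply(polys, nrow, integer(1)),
    in_white_matter = vapply(polys, function(m) any(m[, 3] > cortex_z),
                             logical(1)),
    polyline = polys,
    radii = radii)

  unit$nodes <- n
  unit$entry_point <- ep$point
  unit$segments <- seg
  unit$has_lma_stub <- any(seg$label == "LMA")
  if (is.finite(cortex_z)) unit$penetrates_wm <- any(n$z > cortex_z)
  unit
}

#' Polyline arc length
#'
#' @param polyline numeric matrix, one 3D point (um) per row, >= 2 rows.
#' @return total Euclidean length in um.
#' @export
segment_length <- function(polyline) {
  if (!is.matrix(polyline) || nrow(polyline) < 2) {
    stop("polyline must be a matrix with at least 2 points")
  }
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' External diameter of the D0 segment
#'
#' The D0 segment carries the largest diameter of a unit; its external
#' diameter is summarized as twice the median of the D0 radius samples.
#' The median is robust to local bulges from mural amyloid.
#'
#' @param unit a labeled [vascular_unit], or a numeric vector of D0 radius
#'   samples (um).
#' @return diameter in um, or `NA` when the unit has no D0 segment with at
#'   least 3 radius samples.
#' @export
d0_external_diameter <- function(unit) {
  r <- if (is.numeric(unit)) unit else {
    if (is.null(unit$segments)) return(NA_real_)
    unlist(unit$segments$radii[unit$segments$label == "D0"])
  }
  if (length(r) < 3) return(NA_real_)
  2 * stats::median(r)
}
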