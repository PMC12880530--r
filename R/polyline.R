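# Polyline helpers shared by the rasterizer, classifiers and plaque ops.
# Polylines are n x 3 matrices in um; arc positions are measured from the
# first vertex.

# cumulative arc length at each vertex
arc_positions <- function(poly) {
  d <- diff(poly)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# linear interpolation of points (and optionally radii) at arc positions s
polyline_at <- function(poly, s, radii = NULL) {
  cs <- arc_positions(poly)
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  seg <- findInterval(s, cs, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(poly) - 1L)
  w <- (s - cs[seg]) / pmax(cs[seg + 1] - cs[seg], 1e-12)
  pts <- poly[seg, , drop = FALSE] * (1 - w) +
    poly[seg + 1, , drop = FALSE] * w
  tang <- poly[seg + 1, , drop = FALSE] - poly[seg, , drop = FALSE]
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  out <- list(points = pts, tangents = tang, s = s)
  if (!is.null(radii)) out$radius <- radii[seg] * (1 - w) + radii[seg + 1] * w
  out
}

# resample a polyline (and radii) at a fixed arc step; always includes both
# endpoints' arc range [0, L]
resample_polyline <- function(poly, step, radii = NULL) {
  total <- arc_positions(poly)[nrow(poly)]
  s <- unique(c(seq(0, total, by = step), total))
  polyline_at(poly, s, radii)
}

# orthonormal basis perpendicular to each tangent row; returns list(u, v)
perp_basis <- function(tangents) {
  t1 <- tangents
  ref <- matrix(rep(c(1, 0, 0), each = nrow(t1)), ncol = 3)
  par <- abs(rowSums(t1 * ref)) > 0.9
  ref[par, ] <- matrix(rep(c(0, 1, 0), each = sum(par)), ncol = 3)
  u <- ref - rowSums(ref * t1) * t1
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  v <- cbind(t1[, 2] * u[, 3] - t1[, 3] * u[, 2],
             t1[, 3] * u[, 1] - t1[, 1] * u[, 3],
             t1[, 1] * u[, 2] - t1[, 2] * u[, 1])
  list(u = u, v = v)
}

# concatenate the segment polylines of many units into an edge soup for
# cpp_min_dist_groups; groups = position of the unit in `units`
unit_edge_soup <- function(units, segment_filter = NULL) {
  a <- list(); b <- list(); g <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (is.null(u$segments)) next
    seg <- u$segments
    keep <- if (is.null(segment_filter)) rep(TRUE, nrow(seg)) else
      segment_filter(seg)
    for (j in which(keep)) {
      p <- seg$polyline[[j]]
      if (nrow(p) < 2) next
      a[[length(a) + 1]] <- p[-nrow(p), , drop = FALSE]
      b[[length(b) + 1]] <- p[-1, , drop = FALSE]
      g[[length(g) + 1]] <- rep(i, nrow(p) - 1)
    }
  }
  if (!length(a)) return(NULL)
  list(a = do.call(rbind, a), b = do.call(rbind, b),
       group = unlist(g))
}
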