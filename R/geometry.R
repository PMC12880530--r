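#' Generate the skeleton of one synthetic vascular unit
#'
#' Grows a bifurcating arterial tree entering the cortical slab from the
#' surface plane `z = 0`: a short leptomeningeal (LMA) stub above the
#' surface, then downward-biased growth with a bifurcation after each
#' depth run with probability `branch_prob * branch_decay^depth` (arterial
#' trees branch almost surely near the surface and rarely at depth), up
#' to `max_depth` branching generations. Child diameters taper by `taper` per generation with a
#' hard floor at `diameter_floor_um` (the 8 um arteriole inclusion rule).
#' Growth is clipped laterally to the slab and in depth at the cortical
#' boundary unless the unit is designated white-matter-penetrating.
#'
#' Randomness is taken from the R session RNG; seed it (or use
#' [simulate_cohort()], which seeds once per cohort) for reproducibility.
#'
#' @param params a [cohort_params] object.
#' @param unit_id integer id for the new unit.
#' @param entry_xy length-2 numeric, surface coordinates (um) of the
#'   parenchymal entry; random within the slab when `NULL`.
#' @param root_diameter_um D0 external diameter (um); when `NULL` drawn
#'   lognormal with median `diameter_root_median_neg_um`.
#' @param penetrates_wm logical; when `NULL` drawn with `p_penetrate_wm`.
#' @return an unlabeled [vascular_unit]; `$penetrates_wm` reflects the
#'   designated growth ceiling (and is re-derived from geometry after
#'   labeling).
#' @export
generate_unit_geometry <- function(params, unit_id = 1L, entry_xy = NULL,
                                   root_diameter_um = NULL,
                                   penetrates_wm = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  sx <- params$slab_dims_um[1]; sy <- params$slab_dims_um[2]
  sz <- params$slab_dims_um[3]
  if (is.null(entry_xy)) {
    entry_xy <- c(stats::runif(1, 0.1 * sx, 0.9 * sx),
                  stats::runif(1, 0.1 * sy, 0.9 * sy))
  }
  if (is.null(penetrates_wm)) {
    penetrates_wm <- stats::runif(1) < params$p_penetrate_wm
  }
  if (is.null(root_diameter_um)) {
    root_diameter_um <- stats::rlnorm(
      1, log(params$diameter_root_median_neg_um), params$diameter_sdlog)
  }
  root_diameter_um <- min(max(root_diameter_um, params$diameter_floor_um),
                          params$diameter_cap_um)
  z_max <- if (penetrates_wm) sz - 5 else params$cortex_thickness_um - 5
  step <- params$step_um

  rows <- list()   # each: c(x, y, z, radius, parent_row)
  n_nodes <- 0L
  add_node <- function(p, r, parent) {
    n_nodes <<- n_nodes + 1L
    rows[[n_nodes]] <<- c(p, r, parent)
    n_nodes
  }
  unit_dir <- function(v) v / sqrt(sum(v^2))
  # one run of downward-biased steps; returns index of last node added
  grow_run <- function(from_row, start_pos, dir, radius, len) {
    pos <- start_pos
    parent <- from_row
    n_steps <- max(2L, round(len / step))
    for (k in seq_len(n_steps)) {
      dir <- unit_dir((1 - params$down_bias) * dir +
                        params$down_bias * c(0, 0, 1) +
                        stats::rnorm(3, 0, params$dir_noise))
      if (dir[3] < 0.05) dir <- unit_dir(dir + c(0, 0, 0.4))
      pos <- pos + dir * step
      pos[1] <- min(max(pos[1], 2), sx - 2)
      pos[2] <- min(max(pos[2], 2), sy - 2)
      if (pos[3] > z_max) {
        pos[3] <- z_max
        parent <- add_node(pos, radius, parent)
        return(list(row = parent, dir = dir, clipped = TRUE))
      }
      parent <- add_node(pos, radius, parent)
    }
    list(row = parent, dir = dir, clipped = FALSE)
  }

  # LMA stub: from above the surface down to the entry
  lma_r <- root_diameter_um / 2
  n_lma <- max(2L, round(params$lma_len_um / step))
  top <- c(entry_xy, -params$lma_len_um)
  root <- add_node(top, lma_r, -1L)
  prev <- root
  for (k in seq_len(n_lma)) {
    pz <- -params$lma_len_um * (1 - k / n_lma)
    if (k == n_lma) pz <- step * 0.5   # ensure a crossing of z = 0
    p <- c(entry_xy + stats::rnorm(2, 0, 1.5), pz)
    prev <- add_node(p, lma_r, prev)
  }

  # recursive depth runs
  grow_depth <- function(from_row, pos, dir, radius, depth) {
    len <- max(3 * step,
               stats::rnorm(1, params$seg_len_mean_um, params$seg_len_sd_um))
    res <- grow_run(from_row, pos, dir, radius, len)
    if (res$clipped || depth >= params$max_depth) return(invisible())
    p_branch <- params$branch_prob * params$branch_decay^depth
    if (stats::runif(1) < p_branch) {
      r_child <- max(radius * params$taper, params$diameter_floor_um / 2)
      ang <- stats::runif(1, params$branch_angle_deg[1],
                          params$branch_angle_deg[2]) * pi / 180
      # split plane: random vector perpendicular to dir
      v <- stats::rnorm(3); v <- v - sum(v * res$dir) * res$dir
      v <- v / sqrt(sum(v^2))
      d1 <- unit_dir(cos(ang) * res$dir + sin(ang) * v)
      d2 <- unit_dir(cos(ang) * res$dir - sin(ang) * v)
      last <- rows[[res$row]]
      grow_depth(res$row, last[1:3], d1, r_child, depth + 1L)
      grow_depth(res$row, last[1:3], d2, r_child, depth + 1L)
    }
    invisible()
  }
  start <- rows[[prev]]
  grow_depth(prev, start[1:3], c(0, 0, 1), root_diameter_um / 2, 0L)

  # a designated white-matter-penetrating unit must actually reach the
  # medulla: extend an unbranched continuation from the deepest leaf
  if (penetrates_wm) {
    m0 <- do.call(rbind, rows)
    if (max(m0[, 3]) <= params$cortex_thickness_um) {
      deepest <- which.max(m0[, 3])
      pos <- m0[deepest, 1:3]
      r <- m0[deepest, 4]
      parent <- deepest
      dirv <- c(0, 0, 1)
      while (pos[3] <= params$cortex_thickness_um + 30 && pos[3] < z_max) {
        dirv <- unit_dir(0.7 * dirv + 0.3 * c(0, 0, 1) +
                           stats::rnorm(3, 0, params$dir_noise / 2))
        if (dirv[3] < 0.3) dirv <- unit_dir(dirv + c(0, 0, 0.6))
        pos <- pos + dirv * step
        pos[1] <- min(max(pos[1], 2), sx - 2)
        pos[2] <- min(max(pos[2], 2), sy - 2)
        parent <- add_node(pos, r, parent)
      }
    }
  }

  m <- do.call(rbind, rows)
  nodes <- data.frame(id = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
                      z = m[, 3], radius = m[, 4],
                      parent = as.integer(m[, 5]))
  u <- vascular_unit(nodes, unit_id)
  u$penetrates_wm <- penetrates_wm
  u
}
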