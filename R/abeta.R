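#' Assign ground-truth amyloid deposition to a labeled unit
#'
#' Implements the surface-to-depth deposition model: a unit is
#' amyloid-positive with probability `p_unit_abeta`; if positive, its LMA
#' segment is positive with probability `p_lma_abeta` (independently of
#' the cortical front), and a deposition front depth F is drawn so that
#' P(F >= d) equals `front_reach_probs[d]`. Every cortical segment of
#' depth label <= F is marked positive (a bifurcation segment Dd-Dd+1
#' follows depth d), producing the anatomically contiguous prefix pattern.
#' Rare variants: with probability `p_skip` one deep segment is positive
#' while intermediate cortical segments are negative (LMA or D0 kept
#' positive); with probability `p_wm_confined` positivity is confined to
#' white-matter segments plus LMA/D0. Positive segments carry a deposit
#' run covering `sporadic_fill` of their length (at least 12 um, capped at
#' the segment length), recorded as `abeta_run_start` / `abeta_run_len`
#' for rasterization.
#'
#' @param unit a [vascular_unit] labeled by [label_depths()].
#' @param params a [cohort_params].
#' @param positive optional logical forcing the unit-level draw (used by
#'   [simulate_cohort()], which conditions root diameters on positivity).
#' @return the unit with per-segment truth columns `abeta_positive`,
#'   `abeta_coverage`, `abeta_run_start`, `abeta_run_len` and unit fields
#'   `abeta_positive`, `front_label`, `is_skip`, `is_wm_confined`.
#' @export
assign_abeta <- function(unit, params, positive = NULL) {
  if (is.null(unit$segments)) stop("unit must be labeled by label_depths()")
  seg <- unit$segments
  nseg <- nrow(seg)
  seg$abeta_positive <- rep(FALSE, nseg)
  seg$abeta_coverage <- rep(0, nseg)
  seg$abeta_run_start <- rep(0, nseg)
  seg$abeta_run_len <- rep(0, nseg)
  if (is.null(positive)) positive <- stats::runif(1) < params$p_unit_abeta
  unit$is_skip <- FALSE
  unit$is_wm_confined <- FALSE
  unit$front_label <- NA_character_

  if (positive) {
    rank <- label_rank(seg$label)
    lma_pos <- stats::runif(1) < params$p_lma_abeta
    s <- front_survival(params)
    u <- stats::runif(1)
    front <- if (u > s[1]) -1L else max(which(u <= s)) - 1L
    unit$front_label <- if (front < 0) "none" else depth_label(front)
    pos <- rep(FALSE, nseg)
    pos[seg$label == "LMA"] <- lma_pos
    if (front >= 0) {
      # depth d and bifurcation d-(d+1) positive iff front reaches d
      eff_depth <- ifelse(rank >= 1 & rank < 8, floor(rank - 1 + 1e-9), NA)
      pos[!is.na(eff_depth) & eff_depth <= front] <- TRUE
    }
    deep_rows <- which(rank >= 3 & rank < 8 & !seg$in_white_matter)
    if (stats::runif(1) < params$p_skip && length(deep_rows)) {
      # skip pattern: one deep segment positive, intermediate cortical
      # segments negative, superficial anchor (LMA or D0) retained
      target <- if (length(deep_rows) == 1) deep_rows else
        sample(deep_rows, 1)
      keep_sup <- rank <= 1   # LMA and D0
      pos[!keep_sup] <- FALSE
      pos[target] <- TRUE
      if (!any(pos[keep_sup])) pos[seg$label == "D0"] <- TRUE
      unit$is_skip <- TRUE
      unit$front_label <- "skip"
    } else if (stats::runif(1) < params$p_wm_confined &&
               any(seg$in_white_matter)) {
      pos[rank > 1] <- FALSE
      pos[seg$in_white_matter] <- TRUE
      if (!any(pos[rank <= 1])) pos[seg$label == "D0"] <- TRUE
      unit$is_wm_confined <- TRUE
    }
    seg$abeta_positive <- pos
    if (any(pos)) {
      fill <- params$sporadic_fill
      len <- seg$length_um[pos]
      run <- pmin(len, pmax(12, fill * len))
      start <- stats::runif(sum(pos)) * (len - run)
      seg$abeta_run_len[pos] <- run
      seg$abeta_run_start[pos] <- start
      seg$abeta_coverage[pos] <- run / len
    }
  }
  unit$abeta_positive <- any(seg$abeta_positive)
  unit$segments <- seg
  unit
}

#' Assign ground-truth smooth-muscle-actin loss
#'
#' Only amyloid-positive units may lose SMA (probability `p_sma_loss`).
#' The most superficial lost segment (onset) is drawn from
#' `sma_onset_dist` over the categories LMA / D0 / D1 / deeper,
#' restricted to the unit's amyloid-positive labels and renormalized;
#' loss then applies contiguously from the onset through the deepest
#' amyloid-positive segment, so the lost set is always nested inside the
#' positive set.
#'
#' @inheritParams assign_abeta
#' @return the unit with per-segment `sma_present` and unit field
#'   `sma_loss`.
#' @export
assign_sma_loss <- function(unit, params) {
  seg <- unit$segments
  if (is.null(seg) || is.null(seg$abeta_positive)) {
    stop("run assign_abeta() before assign_sma_loss()")
  }
  seg$sma_present <- rep(TRUE, nrow(seg))
  unit$sma_loss <- FALSE
  if (isTRUE(unit$abeta_positive) && stats::runif(1) < params$p_sma_loss) {
    rank <- label_rank(seg$label)
    pos <- seg$abeta_positive
    # onset categories available on this unit
    cand <- list(
      LMA = any(pos & seg$label == "LMA"),
      D0 = any(pos & seg$label == "D0"),
      D1 = any(pos & seg$label == "D1"),
      deeper = any(pos & rank > 2))
    avail <- names(cand)[unlist(cand)]
    if (length(avail)) {
      w <- params$sma_onset_dist[avail]
      onset_cat <- if (length(avail) == 1) avail else
        sample(avail, 1, prob = w / sum(w))
      onset_rank <- switch(onset_cat,
        LMA = 0, D0 = 1, D1 = 2,
        deeper = min(rank[pos & rank > 2]))
      seg$sma_present[pos & rank >= onset_rank] <- FALSE
      unit$sma_loss <- any(!seg$sma_present)
    }
  }
  unit$segments <- seg
  unit
}
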