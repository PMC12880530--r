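#' Segment depth labels
#'
#' Segments of a vascular unit are labeled by branching order from the
#' cortical entry point: `"LMA"` for the leptomeningeal portion above the
#' entry, `"D0"` for the stretch from entry to the first branch, `"D0-D1"`
#' for the bifurcation region between depths 0 and 1, `"D1"` for the next
#' stretch, and so on up to `"D6"`. Anything deeper than D6 is pooled as
#' `"DEEPER"`. The superficiality order is
#' LMA < D0 < D0-D1 < D1 < ... < D6 < DEEPER.
#'
#' @param label character vector of segment labels.
#' @return `label_rank()` returns a numeric rank increasing with depth
#'   (LMA = 0, D0 = 1, D0-D1 = 1.5, D1 = 2, ..., D6 = 7, DEEPER = 8).
#' @examples
#' label_rank(c("LMA", "D0", "D0-D1", "D1", "DEEPER"))
#' @export
label_rank <- function(label) {
  r <- rep(NA_real_, length(label))
  r[label == "LMA"] <- 0
  r[label == "DEEPER"] <- 8
  depth <- grepl("^D[0-6]$", label)
  r[depth] <- as.numeric(sub("^D", "", label[depth])) + 1
  bif <- grepl("^D[0-5]-D[1-6]$", label)
  r[bif] <- as.numeric(sub("^D([0-5])-D[1-6]$", "\\1", label[bif])) + 1.5
  if (anyNA(r)) {
    stop("unknown segment label(s): ",
         paste(unique(label[is.na(r)]), collapse = ", "))
  }
  r
}

#' @rdname label_rank
#' @details `depth_label(d)` builds the label for integer depth `d`
#'   (`d > 6` gives `"DEEPER"`); `bifurcation_label(d)` the label for the
#'   bifurcation between depths `d` and `d + 1` (pooled into `"DEEPER"`
#'   when `d >= 6`).
#' @param d integer branching depth (0-based).
#' @export
depth_label <- function(d) {
  ifelse(d > 6, "DEEPER", paste0("D", d))
}

#' @rdname label_rank
#' @export
bifurcation_label <- function(d) {
  ifelse(d >= 6, "DEEPER", paste0("D", d, "-D", d + 1))
}

#' All named labels in superficiality order
#' @return character vector from LMA to DEEPER.
#' @export
label_levels <- function() {
  out <- "LMA"
  for (d in 0:6) {
    out <- c(out, paste0("D", d))
    if (d < 6) out <- c(out, paste0("D", d, "-D", d + 1))
  }
  c(out, "DEEPER")
}
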