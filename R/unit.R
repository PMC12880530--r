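#' Vascular unit
#'
#' A vascular unit is one anatomically continuous arterial tree branching
#' from a common leptomeningeal artery (LMA) into the cortex. It is stored
#' as a node table (a traced skeleton) plus, after processing, an entry
#' point, depth-labeled segments and per-segment amyloid / smooth-muscle
#' statuses.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `radius`,
#'   `parent` (`-1` for the root); coordinates in micrometres, surface
#'   plane at `z = 0`, depth increasing with `z`.
#' @param unit_id integer identifier.
#' @return an object of class `vascular_unit`.
#' @export
vascular_unit <- function(nodes, unit_id = 1L) {
  req <- c("id", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns ", paste(req, collapse = ", "))
  }
  if (any(nodes$radius <= 0)) stop("node radii must be > 0")
  if (sum(nodes$parent == -1L) != 1) {
    stop("a vascular unit must have exactly one root")
  }
  known <- nodes$id
  bad <- nodes$parent != -1L & !(nodes$parent %in% known)
  if (any(bad)) stop("dangling parent id(s): ",
                     paste(nodes$parent[bad], collapse = ", "))
  structure(
    list(unit_id = as.integer(unit_id),
         nodes = as.data.frame(nodes),
         entry_point = NULL,
         excluded_reason = NA_character_,
         has_lma_stub = any(nodes$z < 0),
         penetrates_wm = NA,
         segments = NULL,
         abeta_positive = NA,
         sma_loss = NA,
         front_label = NA_character_,
         is_skip = FALSE,
         is_wm_confined = FALSE),
    class = "vascular_unit")
}

#' @export
print.vascular_unit <- function(x, ...) {
  cat("<vascular_unit ", x$unit_id, "> ", nrow(x$nodes), " nodes",
      if (!is.null(x$segments)) paste0(", ", nrow(x$segments), " segments"),
      if (!is.na(x$excluded_reason)) paste0(" [excluded: ",
                                            x$excluded_reason, "]"),
      "\n", sep = "")
  invisible(x)
}

# children index: list mapping row index -> integer row indices of children
children_index <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)   # NA for root
  ch <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    p <- idx[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

#' Tidy segment table of one or many units
#'
#' @param units a `vascular_unit` or list of them (after [label_depths()]).
#' @param geometry keep the polyline/radii list-columns (default `FALSE`).
#' @return a tibble with one row per segment piece.
#' @export
segments_table <- function(units, geometry = FALSE) {
  if (inherits(units, "vascular_unit")) units <- list(units)
  tabs <- lapply(units, function(u) {
    if (is.null(u$segments)) {
      stop("unit ", u$unit_id, " has no segments; run label_depths() first")
    }
    u$segments
  })
  out <- do.call(rbind, tabs)
  if (!geometry) out$polyline <- out$radii <- NULL
  out
}
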