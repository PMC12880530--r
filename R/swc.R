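#' Read and write vessel skeletons in SWC format
#'
#' Standard 7-column SWC (`id type x y z radius parent`), whitespace
#' separated, `#` comments allowed. Coordinates and radii are in
#' micrometres. One vascular unit per root (`parent = -1`). Dialect rules:
#' a parent must be declared before any of its children (forward
#' references are an error), radii must be strictly positive, and parent
#' links must be acyclic. The type column is ignored on read and written
#' as 7 (reserved here for vessels).
#'
#' @param path file path.
#' @return `read_swc()` returns a list of [vascular_unit] objects, one per
#'   root, in order of root declaration.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("SWC file has no data lines: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    stop("SWC parse error at line ", lineno[which(nf != 7)[1]],
         ": expected 7 columns")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("SWC parse error at line ", lineno[bad], ": non-numeric field")
  }
  id <- as.integer(m[, 1]); parent <- as.integer(m[, 7])
  if (anyDuplicated(id)) {
    stop("SWC parse error: duplicated node id ",
         id[anyDuplicated(id)])
  }
  if (any(m[, 6] <= 0)) {
    stop("SWC parse error at line ", lineno[which(m[, 6] <= 0)[1]],
         ": non-positive radius")
  }
  seen <- logical(0)
  seen_ids <- integer(0)
  for (i in seq_along(id)) {
    if (parent[i] != -1 && !(parent[i] %in% seen_ids)) {
      stop("SWC parse error at line ", lineno[i], ": parent ", parent[i],
           " not declared before node ", id[i],
           " (forward/dangling reference)")
    }
    seen_ids <- c(seen_ids, id[i])
  }
  nodes <- data.frame(id = id, x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = parent)
  roots <- which(parent == -1)
  if (!length(roots)) stop("SWC parse error: no root node (parent -1)")
  # assign each node to the unit of its root
  unit_of <- integer(nrow(nodes))
  names(unit_of) <- as.character(id)
  root_idx <- stats::setNames(seq_along(roots), as.character(id[roots]))
  for (i in seq_len(nrow(nodes))) {
    unit_of[i] <- if (parent[i] == -1) {
      root_idx[[as.character(id[i])]]
    } else {
      unit_of[[as.character(parent[i])]]
    }
  }
  lapply(seq_along(roots), function(u) {
    vascular_unit(nodes[unit_of == u, , drop = FALSE], unit_id = u)
  })
}

#' @rdname read_swc
#' @param units list of [vascular_unit] objects.
#' @details `write_swc()` writes nodes in depth-first order from each
#'   root (so parents always precede children, even after processing has
#'   inserted nodes), renumbered consecutively across units, with
#'   coordinates and radii at 6 decimals; `write_swc(read_swc(f))` is
#'   the identity up to float formatting.
#' @export
write_swc <- function(units, path) {
  if (inherits(units, "vascular_unit")) units <- list(units)
  offset <- 0L
  out <- c("# SWC vessel skeleton (type 7 = vessel); coordinates in um",
           "# id type x y z radius parent")
  for (u in units) {
    n <- u$nodes
    ch <- children_index(n)
    root <- which(n$parent == -1L)
    ord <- integer(0); stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ord <- c(ord, v)
      stack <- c(stack, rev(ch[[v]]))
    }
    remap <- integer(nrow(n))
    remap[ord] <- seq_along(ord) + offset
    prow <- match(n$parent, n$id)
    par <- ifelse(is.na(prow), -1L, remap[prow])
    out <- c(out, sprintf("%d 7 %.6f %.6f %.6f %.6f %d",
                          remap[ord], n$x[ord], n$y[ord], n$z[ord],
                          n$radius[ord], par[ord]))
    offset <- offset + nrow(n)
  }
  writeLines(out, path)
  invisible(path)
}
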