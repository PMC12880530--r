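#' Two-channel 3D volume
#'
#' Container for a simulated light-sheet acquisition: an SMA channel and
#' an amyloid channel as depth-major arrays (`dim = c(z, y, x)`), voxel
#' size in um, world origin at (0, 0, 0). Voxel `[i, j, k]` (1-based) is
#' centred at world `((k - 0.5) v, (j - 0.5) v, (i - 0.5) v)` in (x, y, z).
#'
#' @param sma,abeta 3D numeric arrays of identical dimension,
#'   non-negative.
#' @param voxel_size_um positive scalar.
#' @param origin_um world coordinates (x, y, z) of the volume corner
#'   (default `c(0, 0, 0)`). The rasterizer uses a negative z origin so
#'   the leptomeningeal space above the surface plane is inside the
#'   field of view, as in the cleared tissue blocks.
#' @return an object of class `two_channel_volume`.
#' @export
two_channel_volume <- function(sma, abeta, voxel_size_um,
                               origin_um = c(0, 0, 0)) {
  if (!identical(dim(sma), dim(abeta))) {
    stop("sma and abeta channels must have identical dimensions")
  }
  if (length(dim(sma)) != 3) stop("channels must be 3D arrays")
  if (min(sma) < 0 || min(abeta) < 0) {
    stop("channel intensities must be non-negative")
  }
  if (voxel_size_um <= 0) stop("voxel_size_um must be > 0")
  structure(list(sma = sma, abeta = abeta, voxel_size_um = voxel_size_um,
                 origin_um = origin_um),
            class = "two_channel_volume")
}

#' @export
print.two_channel_volume <- function(x, ...) {
  cat("<two_channel_volume>", paste(dim(x$sma), collapse = "x"),
      "voxels (z,y,x) at", x$voxel_size_um, "um\n")
  invisible(x)
}

# world (x,y,z) points -> continuous 0-based voxel coordinates in (z,y,x)
# order, voxel centers at integer coordinates
world_to_vox <- function(points, voxel, origin = c(0, 0, 0)) {
  pts <- sweep(points, 2, origin)
  cbind(pts[, 3], pts[, 2], pts[, 1]) / voxel - 0.5
}

vox_to_world <- function(idx_zyx, voxel, origin = c(0, 0, 0)) {
  # 1-based integer voxel indices -> world (x,y,z) of the voxel center
  sweep(cbind((idx_zyx[, 3] - 0.5), (idx_zyx[, 2] - 0.5),
              (idx_zyx[, 1] - 0.5)) * voxel, 2, -origin)
}

#' Rasterize a ground-truth sample into a two-channel volume
#'
#' Renders vessel walls (solid tubes) into the SMA channel where smooth
#' muscle is present, amyloid wall deposits (tubes thickened by
#' `wall_thickness_um`) over each positive segment's deposit run, Gaussian
#' blobs for plaque spots, elongated perivascular sleeves for dyshoric
#' entries, and dual-channel autofluorescent puncta. A Gaussian PSF blur
#' and optional read/shot noise follow; output is clipped to 16-bit range.
#'
#' @param sample a `gt_sample` from [simulate_cohort()].
#' @param params a [cohort_params] (defaults to `sample$params`).
#' @param cap_voxels refuse to allocate volumes above this many voxels
#'   (default `512^3`); the error names the voxel size that would fit.
#' @return a [two_channel_volume].
#' @export
rasterize <- function(sample, params = sample$params,
                      cap_voxels = 512^3) {
  v <- params$voxel_size_um
  im <- params$imaging
  # extend the field of view above the surface so LMA stubs are imaged
  z_margin <- ceiling((params$lma_len_um + 10) / v) * v
  origin <- c(0, 0, -z_margin)
  ext <- params$slab_dims_um + c(0, 0, z_margin)
  dims <- as.integer(ceiling(ext[c(3, 2, 1)] / v))
  if (prod(dims) > cap_voxels) {
    need <- v * (prod(dims) / cap_voxels)^(1 / 3)
    stop(sprintf(paste0("volume of %d voxels exceeds the cap of %d; ",
                        "increase voxel_size_um to >= %.2f um"),
                 prod(dims), cap_voxels, need))
  }
  sma <- array(0, dims)
  abeta <- array(0, dims)
  step <- v * 0.6

  w <- im$wall_thickness_um
  for (u in sample$units) {
    if (!is.na(u$excluded_reason) || is.null(u$segments)) next
    seg <- u$segments
    for (j in seq_len(nrow(seg))) {
      rs <- resample_polyline(seg$polyline[[j]], step, seg$radii[[j]])
      ctr <- world_to_vox(rs$points, v, origin)
      if (isTRUE(seg$sma_present[j])) {
        cpp_stamp_spheres(sma, dims, ctr, rs$radius / v, im$sma_level)
      }
      if (isTRUE(seg$abeta_positive[j])) {
        # deposits are painted as capped cylinder chains so the wall
        # signal ends exactly at the deposit-run boundary and cannot
        # spill a scoreable run onto an adjacent negative segment
        s0 <- seg$abeta_run_start[j]
        s1 <- s0 + seg$abeta_run_len[j]
        sw <- unique(pmin(pmax(rs$s, s0), s1))
        if (length(sw) >= 2) {
          at <- polyline_at(seg$polyline[[j]], sw, seg$radii[[j]])
          cw <- world_to_vox(at$points, v, origin)
          n <- nrow(cw)
          rr <- (at$radius[-n] + at$radius[-1]) / 2 + w
          cpp_stamp_cylinders(abeta, dims, cw[-n, , drop = FALSE],
                              cw[-1, , drop = FALSE], rr / v,
                              im$abeta_wall_level)
        }
      }
    }
  }
  # dyshoric sleeves: solid tubes out to the annulus outer radius
  if (nrow(sample$dyshoric)) {
    by_id <- stats::setNames(sample$units,
                             vapply(sample$units,
                                    function(u) as.character(u$unit_id),
                                    character(1)))
    for (i in seq_len(nrow(sample$dyshoric))) {
      dy <- sample$dyshoric[i, ]
      u <- by_id[[as.character(dy$unit_id)]]
      seg <- u$segments
      j <- match(dy$seg_id, seg$seg_id)
      s <- seq(dy$start_um, dy$start_um + dy$length_um, by = step)
      at <- polyline_at(seg$polyline[[j]], s, seg$radii[[j]])
      cw <- world_to_vox(at$points, v, origin)
      n <- nrow(cw)
      rr <- (at$radius[-n] + at$radius[-1]) / 2 + dy$r_out_um
      cpp_stamp_cylinders(abeta, dims, cw[-n, , drop = FALSE],
                          cw[-1, , drop = FALSE], rr / v, im$sleeve_level)
    }
  }
  # plaque spots as solid spheres (plaques are modeled as spheres)
  if (nrow(sample$spots)) {
    ctr <- world_to_vox(as.matrix(sample$spots[, c("x_um", "y_um", "z_um")]),
                        v, origin)
    cpp_stamp_spheres(abeta, dims, ctr, sample$spots$radius_um / v,
                      im$spot_level)
  }
  # dual-channel autofluorescent puncta
  n_punc <- stats::rpois(1, params$artifact_puncta_density *
                           prod(params$slab_dims_um))
  if (n_punc > 0) {
    pw <- cbind(stats::runif(n_punc, 0, params$slab_dims_um[1]),
                stats::runif(n_punc, 0, params$slab_dims_um[2]),
                stats::runif(n_punc, 0, params$slab_dims_um[3]))
    pc <- world_to_vox(pw, v, origin)
    sg <- rep(im$puncta_sigma_um / v, n_punc)
    cpp_stamp_gaussians(abeta, dims, pc, sg, rep(im$puncta_level, n_punc))
    cpp_stamp_gaussians(sma, dims, pc, sg, rep(im$puncta_level, n_punc))
  }
  sma <- sma + im$background
  abeta <- abeta + im$background
  if (im$psf_sigma_um > 0) {
    sma <- cpp_gauss3d(sma, dims, im$psf_sigma_um / v)
    abeta <- cpp_gauss3d(abeta, dims, im$psf_sigma_um / v)
  }
  addnoise <- function(a) {
    if (im$shot_noise_gain > 0) {
      a <- stats::rpois(length(a), pmax(a, 0) / im$shot_noise_gain) *
        im$shot_noise_gain
      dim(a) <- dims
    }
    if (im$read_noise_sd > 0) {
      a <- a + stats::rnorm(length(a), 0, im$read_noise_sd)
      dim(a) <- dims
    }
    a
  }
  sma <- addnoise(sma); abeta <- addnoise(abeta)
  clip <- function(a) { a[a < 0] <- 0; a[a > 65535] <- 65535; round(a) }
  two_channel_volume(clip(sma), clip(abeta), v, origin)
}

#' Estimate a vessel radius profile from the SMA channel
#'
#' Binarizes the SMA channel at a threshold, computes the 3D Euclidean
#' distance transform of the foreground, and reads the transform at
#' centerline points sampled every 2 um: at the centerline of a filled
#' tube the distance to background (plus half a voxel, since the wall
#' boundary lies between voxel centers) equals the tube radius. Points
#' falling outside the foreground get radius 0.
#'
#' @param volume a [two_channel_volume] (or bare 3D array with `voxel`).
#' @param polyline centerline, n x 3 matrix in um.
#' @param binarize_threshold intensity threshold for foreground.
#' @param voxel voxel size in um (taken from `volume` if it is a
#'   [two_channel_volume]).
#' @param step_um centerline sampling step (default 2).
#' @return numeric vector of radii (um) at the sampled points.
#' @export
estimate_radius_profile <- function(volume, polyline, binarize_threshold,
                                    voxel = NULL, step_um = 2) {
  origin <- c(0, 0, 0)
  if (inherits(volume, "two_channel_volume")) {
    voxel <- volume$voxel_size_um
    origin <- volume$origin_um
    a <- volume$sma
  } else {
    if (is.null(voxel)) stop("voxel size required for a bare array")
    a <- volume
  }
  dims <- dim(a)
  fg <- (a > binarize_threshold) * 1
  if (!any(fg > 0)) {
    warning("empty foreground after binarization; all radii are zero")
    n <- length(resample_polyline(polyline, step_um)$s)
    return(rep(0, n))
  }
  dist <- cpp_edt3d(fg, as.integer(dims))
  rs <- resample_polyline(polyline, step_um)
  idx <- round(world_to_vox(rs$points, voxel, origin)) + 1
  idx[, 1] <- pmin(pmax(idx[, 1], 1), dims[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1), dims[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1), dims[3])
  d <- dist[cbind(idx[, 1], idx[, 2], idx[, 3])]
  # the wall lies half a voxel beyond the last foreground voxel center
  ifelse(d > 0, (d + 0.5) * voxel, 0)
}

#' Write / read a two-channel volume as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_sma.tif`,
#' `<prefix>_abeta.tif`, one page per z slice) plus a JSON sidecar with
#' the voxel size. Requires the `tiff` package.
#'
#' @param volume a [two_channel_volume].
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_volume_tiff <- function(volume, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF volumes")
  }
  wr <- function(a, path) {
    pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  wr(volume$sma, paste0(prefix, "_sma.tif"))
  wr(volume$abeta, paste0(prefix, "_abeta.tif"))
  side <- paste0(prefix, "_volume.json")
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size_um,
                            origin_um = volume$origin_um,
                            dim_zyx = dim(volume$sma),
                            axis_order = "zyx"),
                       side, auto_unbox = TRUE)
  invisible(side)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF volumes")
  }
  side <- jsonlite::read_json(paste0(prefix, "_volume.json"),
                              simplifyVector = TRUE)
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    a <- array(0, side$dim_zyx)
    for (i in seq_along(pages)) a[i, , ] <- round(pages[[i]] * 65535)
    a
  }
  two_channel_volume(rd(paste0(prefix, "_sma.tif")),
                     rd(paste0(prefix, "_abeta.tif")),
                     side$voxel_size_um,
                     if (is.null(side$origin_um)) c(0, 0, 0) else side$origin_um)
}
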