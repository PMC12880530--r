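#' Cohort generative model parameters
#'
#' Builds and validates the full parameter set of the synthetic CAA cohort
#' generator. Defaults are calibrated to the published study conditions
#' wherever a value is printed; purely geometric tree-growth controls
#' (step sizes, branch angles, segment lengths) have no published values
#' and carry invented defaults, documented in the methods vignette.
#'
#' Key calibrated defaults:
#' * `front_reach_probs`: survival function of the deposition front over
#'   depths D0..D6, i.e. P(front reaches depth d | unit positive). The
#'   default is the printed per-segment load profile (99.5, 45.8, 19.8,
#'   10.0, 4.5, 6.3, 0 percent) made non-increasing by a running minimum
#'   (the printed D5 rate exceeds D4 and cannot be a survival value).
#' * `p_lma_abeta = 0.962`, `p_unit_abeta = 1104/1639`,
#'   `p_sma_loss = 547/1104`, `p_dyshoric_unit = 0.127`,
#'   `dyshoric_d0_share = 0.915`, `p_skip = 11/1104`.
#' * D0 diameter medians 36.73 / 25.94 um for amyloid-positive / negative
#'   units; lognormal spread `diameter_sdlog = 0.3` reproduces the printed
#'   interquartile ranges.
#' * `diameter_floor_um = 8`: vessels thinner than 8 um are below the
#'   arteriole inclusion rule and are never generated.
#'
#' @param ... named overrides of any default listed in `cohort_params()`.
#' @param strict logical; when `TRUE` (default) a non-increasing
#'   `front_reach_probs` is required and a violation is an error. With
#'   `strict = FALSE` the vector is monotonized internally (running
#'   minimum) before sampling.
#' @return an object of class `cohort_params` (a validated named list).
#' @examples
#' p <- cohort_params(n_units = 10, seed = 1)
#' p$front_reach_probs
#' @export
cohort_params <- function(..., strict = TRUE) {
  defaults <- list(
    # -- slab geometry (um), surface plane at z = 0, depth = +z
    slab_dims_um       = c(1500, 1500, 1200),
    voxel_size_um      = 2,
    cortex_thickness_um = 900,
    # -- cohort composition
    n_units            = 60,
    p_unit_abeta       = 1104 / 1639,
    p_lma_abeta        = 0.962,
    front_reach_probs  = c(D0 = 0.995, D1 = 0.458, D2 = 0.198, D3 = 0.100,
                           D4 = 0.045, D5 = 0.045, D6 = 0),
    p_skip             = 11 / 1104,
    p_wm_confined      = 0.005,
    sporadic_fill      = 0.6,
    # -- smooth-muscle-actin loss
    p_sma_loss         = 547 / 1104,
    sma_onset_dist     = c(LMA = 0.65, D0 = 0.30, D1 = 0.04, deeper = 0.01),
    # -- morphometry
    diameter_root_median_pos_um = 36.73,
    diameter_root_median_neg_um = 25.94,
    diameter_sdlog     = 0.3,
    diameter_floor_um  = 8,
    diameter_cap_um    = 60,
    taper              = 0.8,
    # -- tree growth (invented; no published branching statistics)
    branch_prob        = 0.95,
    branch_decay       = 0.6,
    seg_len_mean_um    = 200,
    seg_len_sd_um      = 60,
    max_depth          = 6,
    step_um            = 12,
    lma_len_um         = 80,
    dir_noise          = 0.22,
    down_bias          = 0.15,
    branch_angle_deg   = c(25, 45),
    p_penetrate_wm     = 0.3,
    # -- parenchymal plaques
    plaque_lambda0     = 3.7e-6,    # plaques per um^3 of cortex
    plaque_thinning_theta = 0.85,   # retention near positive units
    plaque_radius_um   = c(meanlog = log(15), sdlog = 0.25),
    # -- dyshoric change
    p_dyshoric_unit    = 0.127,
    dyshoric_d0_share  = 0.915,
    dyshoric_len_um    = c(meanlog = log(80), sdlog = 0.3),
    # -- imaging artifacts / rasterization
    artifact_puncta_density = 2e-8, # puncta per um^3, both channels
    imaging = list(
      psf_sigma_um      = 1.5,
      background        = 500,
      sma_level         = 30000,
      abeta_wall_level  = 28000,
      spot_level        = 20000,
      sleeve_level      = 24000,
      puncta_level      = 26000,
      puncta_sigma_um   = 4,
      wall_thickness_um = 4,
      read_noise_sd     = 0,
      shot_noise_gain   = 0
    ),
    seed               = 1L
  )
  over <- list(...)
  if (anyDuplicated(names(over))) {
    stop("duplicated cohort parameter(s): ",
         paste(unique(names(over)[duplicated(names(over))]),
               collapse = ", "))
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown cohort parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- defaults
  for (nm in names(over)) {
    if (nm == "imaging") {
      stopifnot(is.list(over$imaging))
      p$imaging[names(over$imaging)] <- over$imaging
    } else {
      p[[nm]] <- over[[nm]]
    }
  }
  p$strict <- isTRUE(strict)
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      stop(nm, " must be a probability in [0, 1]")
    }
  }
  for (nm in c("p_unit_abeta", "p_lma_abeta", "p_skip", "p_wm_confined",
               "sporadic_fill", "p_sma_loss", "p_dyshoric_unit",
               "dyshoric_d0_share", "plaque_thinning_theta",
               "p_penetrate_wm", "branch_prob")) {
    chk_prob(p[[nm]], nm)
  }
  chk_prob(p$front_reach_probs, "front_reach_probs")
  if (length(p$front_reach_probs) != 7) {
    stop("front_reach_probs must have 7 entries (D0..D6)")
  }
  if (p$strict && any(diff(p$front_reach_probs) > 1e-12)) {
    stop("front_reach_probs must be non-increasing from D0 to D6 ",
         "(a survival function); pass strict = FALSE to monotonize")
  }
  chk_prob(p$sma_onset_dist, "sma_onset_dist")
  if (!setequal(names(p$sma_onset_dist), c("LMA", "D0", "D1", "deeper"))) {
    stop("sma_onset_dist must be named LMA, D0, D1, deeper")
  }
  if (p$diameter_floor_um < 8) {
    stop("diameter_floor_um must be >= 8 (arteriole inclusion rule)")
  }
  if (p$diameter_cap_um <= p$diameter_floor_um) {
    stop("diameter_cap_um must exceed diameter_floor_um")
  }
  if (any(p$slab_dims_um <= 0) || p$voxel_size_um <= 0 ||
      p$cortex_thickness_um <= 0) {
    stop("slab, voxel and cortex sizes must be strictly positive")
  }
  if (p$cortex_thickness_um >= p$slab_dims_um[3]) {
    stop("cortex_thickness_um must be smaller than the slab z extent")
  }
  if (p$plaque_lambda0 < 0) stop("plaque_lambda0 must be >= 0")
  if (p$taper <= 0 || p$taper > 1) stop("taper must be in (0, 1]")
  if (p$n_units < 1) stop("n_units must be >= 1")
  invisible(p)
}

# survival function over depths 0..6 used for front sampling; monotonized
# when the strict flag is off
front_survival <- function(p) {
  s <- as.numeric(p$front_reach_probs)
  if (any(diff(s) > 1e-12)) {
    if (p$strict) {
      stop("front_reach_probs is not a valid survival function")
    }
    s <- cummin(s)
  }
  s
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>", x$n_units, "units, slab",
      paste(x$slab_dims_um, collapse = "x"), "um, seed", x$seed, "\n")
  invisible(x)
}
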