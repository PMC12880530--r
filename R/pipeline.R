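#' Default run configuration
#'
#' Nested list with one block per pipeline stage: `cohort` (overrides
#' passed to [cohort_params()]), `classify` (intensity threshold and
#' run/gap rules), `plaques` (band, spot detection, artifact ratio,
#' dyshoric rules), `meta` (sample labels) and `seed`. Serialize with
#' [yaml::write_yaml()]; [run_all()] accepts either the list or a YAML
#' path.
#'
#' @param seed integer root seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(),
    classify = list(intensity_threshold = 5000, run_min_um = 10,
                    gap_max_um = 20, wall_band = c(0, 6)),
    plaques = list(band = c(10, 100), spot_diameter_um = 50,
                   quality_min = 2000, ratio_alpha = 0.8,
                   dyshoric_coverage_min = 0.5,
                   dyshoric_length_min_um = 50),
    meta = list(sample_id = "S1", region = "frontal", caa_type = 1)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  for (blk in names(base)) {
    if (blk %in% names(config)) {
      if (is.list(base[[blk]])) {
        # cohort fields are validated by cohort_params(); other blocks
        # must match the default schema exactly
        if (blk != "cohort" && length(setdiff(names(config[[blk]]),
                                              names(base[[blk]])))) {
          stop("unknown field(s) in config block '", blk, "': ",
               paste(setdiff(names(config[[blk]]), names(base[[blk]])),
                     collapse = ", "))
        }
        base[[blk]][names(config[[blk]])] <- config[[blk]]
      } else {
        base[[blk]] <- config[[blk]]
      }
    }
  }
  extra <- setdiff(names(config), names(base))
  if (length(extra)) stop("unknown config block(s): ",
                          paste(extra, collapse = ", "))
  base
}

#' Run the full pipeline on one synthetic sample
#'
#' simulate -> label -> classify -> plaques -> stats, writing all
#' artifacts under `out`: the cohort (SWC + truth tables + params echo),
#' `unit_status.csv`, `load_summary.json`, `densities.csv`,
#' `dyshoric.csv` and a `report/` directory. Outputs are pure functions
#' of (config, seed). With `truth_only = TRUE` (default) classification
#' uses the generator's ground-truth statuses; otherwise the sample is
#' rasterized and statuses are measured from the volume (set
#' `raster = TRUE` to also write the TIFF volume).
#'
#' @param config configuration list or YAML path (see
#'   [default_config()]).
#' @param out output directory.
#' @param truth_only classify from ground truth instead of the raster.
#' @param raster write the rasterized volume as TIFF.
#' @return list with `sample`, `status`, `load`, `densities`,
#'   `dyshoric`, `report` (invisibly).
#' @export
run_all <- function(config = default_config(), out = tempfile("caa3d_run_"),
                    truth_only = TRUE, raster = FALSE) {
  cfg <- read_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  params <- stage("simulate", do.call(
    cohort_params, c(cfg$cohort, list(seed = cfg$seed))))
  sample <- stage("simulate", simulate_cohort(params))
  stage("simulate", write_cohort(sample, file.path(out, "cohort")))

  volume <- NULL
  if (!truth_only || raster) {
    volume <- stage("rasterize", rasterize(sample))
    if (raster) {
      stage("rasterize",
            write_volume_tiff(volume, file.path(out, "volume")))
    }
  }
  cl <- cfg$classify
  if (truth_only) {
    status <- segments_table(
      Filter(function(u) is.na(u$excluded_reason), sample$units))
    status <- status[, c("unit_id", "seg_id", "label", "abeta_positive",
                         "abeta_coverage", "sma_present")]
    load <- vascular_load(status)
  } else {
    res <- stage("classify", classify_units(
      volume, sample$units, cl$intensity_threshold, cl$wall_band,
      cl$run_min_um, cl$gap_max_um))
    status <- res$status
    load <- res$load
  }
  utils::write.csv(status, file.path(out, "unit_status.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, sample_id = cfg$meta$sample_id,
         n_units = load$n_units, n_positive = load$n_positive,
         load_fraction = load$load_fraction, load_class = load$load_class,
         per_segment_rates = load$per_segment_rates),
    file.path(out, "load_summary.json"), auto_unbox = TRUE, digits = NA)

  pq <- cfg$plaques
  spots <- if (truth_only) {
    sample$spots
  } else {
    stage("plaques", exclude_artifacts(
      detect_spots(volume, pq$spot_diameter_um, pq$quality_min),
      volume, pq$spot_diameter_um, pq$ratio_alpha))
  }
  dens <- stage("plaques", perivascular_density_table(
    sample$units, spots, params$cortex_thickness_um, pq$band))
  utils::write.csv(dens, file.path(out, "densities.csv"),
                   row.names = FALSE)
  dysh <- stage("plaques", attribute_dyshoric(sample$units,
                                              sample$dyshoric))
  utils::write.csv(dysh, file.path(out, "dyshoric.csv"),
                   row.names = FALSE)

  unit_pos <- tapply(status$abeta_positive, status$unit_id, any)
  by_id <- stats::setNames(sample$units,
                           vapply(sample$units,
                                  function(u) as.character(u$unit_id),
                                  character(1)))
  unit_table <- tibble::tibble(
    sample_id = cfg$meta$sample_id,
    unit_id = as.integer(names(unit_pos)),
    abeta_positive = as.logical(unit_pos),
    d0_diameter_um = vapply(names(unit_pos), function(i)
      d0_external_diameter(by_id[[i]]), numeric(1)))
  unit_table <- merge(unit_table, dens[, c("unit_id", "density_per_um")],
                      by = "unit_id", all.x = TRUE)
  status$sample_id <- cfg$meta$sample_id
  meta <- tibble::tibble(sample_id = cfg$meta$sample_id,
                         region = cfg$meta$region,
                         caa_type = cfg$meta$caa_type)
  report <- stage("stats", build_report(unit_table, status, meta))
  stage("stats", write_report(report, file.path(out, "report")))
  invisible(list(sample = sample, status = status, load = load,
                 densities = dens, dyshoric = dysh, report = report,
                 out = out))
}

#' Build versioned test fixtures
#'
#' `tiny`: 5 units, truth tables only, no raster. `small`: 60 units on a
#' 1024 x 1024 x 512 um slab at 4 um voxels (256 x 256 x 128 raster)
#' exercising every label from LMA to D3. Fixed seeds make fixture
#' content stable across runs.
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir optional directory; when given, the cohort (and for
#'   `small`, the volume TIFF) is written there.
#' @return list with `sample`, `params` and (for `small`) `volume`.
#' @export
make_fixtures <- function(size = c("tiny", "small"), dir = NULL) {
  size <- match.arg(size)
  params <- if (size == "tiny") {
    cohort_params(slab_dims_um = c(400, 400, 300),
                  cortex_thickness_um = 220, n_units = 5,
                  voxel_size_um = 4, seg_len_mean_um = 80,
                  seg_len_sd_um = 20, step_um = 12, branch_prob = 0.9,
                  branch_decay = 1, p_penetrate_wm = 0.2, plaque_lambda0 = 2e-6,
                  dir_noise = 0.1, down_bias = 0.35, seed = 101L)
  } else {
    cohort_params(slab_dims_um = c(1200, 1200, 512),
                  cortex_thickness_um = 400, n_units = 60,
                  voxel_size_um = 4, seg_len_mean_um = 95,
                  seg_len_sd_um = 20, step_um = 12, branch_prob = 0.85,
                  branch_decay = 1, max_depth = 3, taper = 0.85, p_penetrate_wm = 0.15,
                  plaque_lambda0 = 1e-6, lma_len_um = 60,
                  dir_noise = 0.1, down_bias = 0.35,
                  branch_angle_deg = c(40, 55),
                  artifact_puncta_density = 0, seed = 202L)
  }
  sample <- simulate_cohort(params)
  out <- list(sample = sample, params = params)
  if (size == "small") out$volume <- rasterize(sample)
  if (!is.null(dir)) {
    write_cohort(sample, dir)
    if (size == "small" && requireNamespace("tiff", quietly = TRUE)) {
      write_volume_tiff(out$volume, file.path(dir, "volume"))
    }
  }
  out
}
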