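# Shared helpers: hand-built skeletons, status tables, and a per-session
# cache for the expensive rasterized fixture.

# straight vertical unit crossing the surface at (x, y, 0); radius constant
chain_unit <- function(x = 100, y = 100, z_top = -40, z_bottom = 300,
                       radius = 16, step = 10, unit_id = 1L) {
  z <- seq(z_top, z_bottom, by = step)
  n <- length(z)
  vascular_unit(data.frame(
    id = seq_len(n), x = x, y = y, z = z, radius = radius,
    parent = c(-1L, seq_len(n - 1))), unit_id)
}

# one bifurcation: vertical trunk, then two diverging children
fork_unit <- function(radius = 16, unit_id = 1L) {
  z_tr <- seq(-40, 150, by = 10)
  n <- length(z_tr)
  trunk <- data.frame(id = seq_len(n), x = 200, y = 200, z = z_tr,
                      radius = radius, parent = c(-1L, seq_len(n - 1)))
  child <- function(id0, dx, parent) {
    k <- 12
    data.frame(id = id0 + seq_len(k),
               x = 200 + dx * seq_len(k) * 7,
               y = 200,
               z = 150 + seq_len(k) * 8,
               radius = radius * 0.8,
               parent = c(parent, id0 + seq_len(k - 1)))
  }
  vascular_unit(rbind(trunk, child(n, +1, n), child(n + 12, -1, n)),
                unit_id)
}

# minimal segment-status table for status-logic tests
status_df <- function(labels, parents, abeta, unit_id = 1L) {
  tibble::tibble(unit_id = unit_id, seg_id = seq_along(labels),
                 label = labels, parent_seg = parents,
                 abeta_positive = abeta)
}

# fast generator settings for property tests; overrides replace defaults
fast_params <- function(...) {
  args <- list(slab_dims_um = c(800, 800, 700),
               cortex_thickness_um = 500, n_units = 20,
               seg_len_mean_um = 110, seg_len_sd_um = 30,
               step_um = 16, max_depth = 4, plaque_lambda0 = 0,
               artifact_puncta_density = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_params, args)
}

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- make_fixtures("small")
  }
  .fixture_cache$small
}
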