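#!/usr/bin/env Rscript

# Assembles the grouped statistical report: quartile tables and
# Mann-Whitney / Kruskal-Wallis / Steel-Dwass comparisons of D0
# diameters and perivascular densities across amyloid status, region,
# load class and CAA type.

library(caa3d)

plan <- read.csv("results/cohort_plan.csv")
diam <- read.csv("results/diameters.csv")
dens <- read.csv("results/densities.csv")
onset <- read.csv("results/sma_onset.csv")

unit_table <- merge(diam,
                    dens[, c("sample_id", "unit_id", "density_per_um")],
                    by = c("sample_id", "unit_id"), all.x = TRUE)

message("most-superficial-SMA-loss counts per sample:")
print(table(onset$sample_id, onset$onset_label))

segment_status <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
  p <- cohort_params(slab_dims_um = c(2000, 2000, 1200),
                     n_units = plan$n_units[i],
                     p_unit_abeta = plan$p_unit_abeta[i],
                     seed = plan$seed[i])
  st <- segments_table(Filter(function(u) is.na(u$excluded_reason),
                              simulate_cohort(p)$units))
  data.frame(sample_id = plan$sample_id[i], unit_id = st$unit_id,
             label = st$label, abeta_positive = st$abeta_positive)
}))

meta <- plan[, c("sample_id", "region", "caa_type")]
report <- build_report(unit_table, segment_status, meta)
write_report(report, "results/report")

message("sample loads:")
print(report$sample_loads)
message("D0 diameter, amyloid-positive vs negative (overall):")
print(report$diameter$overall$quartiles)
print(report$diameter$overall$test)
message("perivascular density, amyloid-positive vs negative (overall):")
print(report$density$overall$quartiles)
print(report$density$overall$test)
if (!is.null(report$density_by_load)) {
  message("density across load classes (Kruskal-Wallis + Steel-Dwass):")
  print(report$density_by_load$kruskal)
  print(report$density_by_load$steel_dwass)
}
message("report written to results/report/")
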