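#!/usr/bin/env Rscript

# Reads the traced skeletons back from SWC, resolves each unit's
# parenchymal entry point, labels segments by branching depth (LMA, D0,
# D0-D1, ...), and checks the labeling against the truth tables written
# by 01_simulate.R: the re-derived label partition must cover the whole
# intraparenchymal skeleton and agree with the stored segment table.

library(caa3d)

plan <- read.csv("results/cohort_plan.csv")
rows <- list()
for (i in seq_len(nrow(plan))) {
  dir <- file.path("results/cohort", plan$sample_id[i])
  truth <- read.csv(file.path(dir, "segments.csv"))
  p <- yaml::read_yaml(file.path(dir, "params.yaml"))
  swc <- list.files(dir, pattern = "\\.swc$", full.names = TRUE)
  n_excluded <- 0L; worst_resid <- 0
  labs <- character(0)
  for (f in swc) {
    for (u in read_swc(f)) {
      lu <- label_depths(u, cortex_z = p$cortex_thickness_um)
      if (!is.na(lu$excluded_reason)) { n_excluded <- n_excluded + 1L; next }
      seg <- lu$segments
      labs <- c(labs, seg$label)
      below <- seg$label != "LMA"
      tot <- sum(seg$length_um[below])
      # truth table for the same unit id (file name carries the id)
      uid <- as.integer(sub(".*unit_(\\d+)\\.swc", "\\1", f))
      tt <- truth[truth$unit_id == uid & truth$label != "LMA", ]
      worst_resid <- max(worst_resid,
                         abs(tot - sum(tt$length_um)) / max(tot, 1))
    }
  }
  rows[[i]] <- data.frame(sample_id = plan$sample_id[i],
                          n_swc = length(swc), n_excluded = n_excluded,
                          n_labels = length(unique(labs)),
                          deepest = labs[which.max(label_rank(labs))],
                          max_partition_residual = worst_resid)
  message(sprintf("%s: %d skeletons, %d excluded, deepest label %s, partition residual %.2g",
                  plan$sample_id[i], length(swc), n_excluded,
                  rows[[i]]$deepest, worst_resid))
}
qc <- do.call(rbind, rows)
write.csv(qc, "results/labeling_qc.csv", row.names = FALSE)
stopifnot(all(qc$max_partition_residual < 1e-6))
message("labeling round-trip clean for all samples")
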