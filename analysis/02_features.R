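#!/usr/bin/env Rscript
# Step 2: sweep the parameter grid and extract all five GSP feature types.
#
# Grid per combination: edge property (NFD/NF/MFL/MFA) x structural
# individuality (group/subject connectome) x shift operator
# (L_U/L_N/L_RW/L_Q) x temporal z-scoring x spectral normalization, plus the
# feature-specific factor (retained harmonics nH for alignment/liberality,
# cutoff scheme f1-f4 for the SDI). PSD, energy and SDI use their full grids
# (128, 128, 512 combinations); for alignment and liberality the 10-point nH
# grid is thinned to its endpoints (5% and 20% of R, 256 combinations each)
# to keep the sweep at desk scale.
#
# Output: scratch/tables.rds (feature tables for the three parcellation
# variants) and a per-type summary CSV.

library(gspfinger)

cohort <- readRDS("scratch/cohort.rds")
R <- cohort$config$n_regions

grids <- list(
  PSD = enumerate_combinations("PSD", R),
  energy = enumerate_combinations("energy", R),
  alignment = {
    g <- enumerate_combinations("alignment", R)
    g[g$nH_pct %in% c(0.05, 0.20), ]
  },
  liberality = {
    g <- enumerate_combinations("liberality", R)
    g[g$nH_pct %in% c(0.05, 0.20), ]
  },
  SDI = enumerate_combinations("SDI", R)
)

tables <- list()
summary_rows <- list()
for (ft in names(grids)) {
  t0 <- Sys.time()
  for (variant in c("S3", "S3minus", "S1")) {
    tables[[ft]][[variant]] <- suppressWarnings(
      compute_feature_table(cohort, ft, combos = grids[[ft]], variant = variant))
  }
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  n_combo <- nrow(grids[[ft]])
  cat(sprintf("%-10s %4d combinations x %d scans x 3 variants  (%.1f s)\n",
              ft, n_combo, nrow(cohort$meta), dt))
  summary_rows[[ft]] <- data.frame(feature_type = ft, n_combinations = n_combo,
                                   n_scans = nrow(cohort$meta),
                                   seconds = round(dt, 1))
}

saveRDS(tables, "scratch/tables.rds")
utils::write.csv(do.call(rbind, summary_rows),
                 "results/analysis/feature_sweep_summary.csv", row.names = FALSE)
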