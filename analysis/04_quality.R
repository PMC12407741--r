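#!/usr/bin/env Rscript
# Step 4: score every feature type x parameter combination on the six
# quality criteria:
#   - percentage of incongruent subjects (same-day similarity lower than
#     different-day similarity; lower is better), with the penalty Omega as
#     an intermediate,
#   - mean FD-explained variance within the fingerprinting coefficients
#     (lower is better),
#   - ICC(A,1) within the fingerprinting coefficients (higher is better),
#   - maximal fingerprinting accuracy after ICC-ranked selection (selection
#     on the LR sessions, evaluation on the RL day pair; higher is better),
#   - percentage of coefficients needed for that maximum (lower is better),
#   - mean absolute accuracy change under the S3->S3- and S3->S1
#     parcellation switches (lower is better).
#
# Output: results/analysis/quality_<feature>.csv.

library(gspfinger)

tables <- readRDS("scratch/tables.rds")

for (ft in names(tables)) {
  t0 <- Sys.time()
  rep <- suppressWarnings(quality_report(
    tables[[ft]]$S3,
    table_s3minus = tables[[ft]]$S3minus,
    table_s1 = tables[[ft]]$S1,
    stride = 2
  ))
  num <- vapply(rep, is.numeric, logical(1))
  rep[num] <- lapply(rep[num], round, digits = 5)
  utils::write.csv(rep, sprintf("results/analysis/quality_%s.csv", ft),
                   row.names = FALSE)
  cat(sprintf(
    "%-10s best accuracy %.0f%% (%d/%d combos at 100%%); median P_inc %.0f%%  (%.0f s)\n",
    ft, max(rep$accuracy_max), sum(rep$accuracy_max == 100), nrow(rep),
    stats::median(rep$pct_incongruent),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}
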