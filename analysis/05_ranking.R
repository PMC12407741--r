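#!/usr/bin/env Rscript
# Step 5: consensus ranking of all candidate pipelines.
#
# The six criteria are concatenated over every feature type x parameter
# combination, min-max normalized to [0, 100] with orientation flipped where
# lower is better, and averaged into a consensus score. The top rows are the
# package's practical recommendation on this cohort; the `top20_accuracy`
# flag marks, per feature type, the 20 cases with the best selected-subset
# accuracy (spider-plot export).
#
# Output: results/analysis/ranking.csv; top-10 printed.

library(gspfinger)

files <- Sys.glob("results/analysis/quality_*.csv")
reports <- do.call(rbind, lapply(files, function(f) {
  d <- utils::read.csv(f)
  cols <- c("feature_type", "combo_id", "property", "individuality", "operator",
            "zscore", "normalize", "pct_incongruent", "pfd_selected",
            "icc_selected", "accuracy_max", "pct_coeffs_used",
            "generalization_change")
  d[, cols]
}))

ranked <- suppressWarnings(rank_pipelines(reports))
num <- vapply(ranked, is.numeric, logical(1))
ranked[num] <- lapply(ranked[num], round, digits = 4)
utils::write.csv(ranked, "results/analysis/ranking.csv", row.names = FALSE)

cat("Top 10 pipelines by consensus score:\n")
top <- ranked[1:10, c("feature_type", "property", "individuality", "operator",
                      "zscore", "normalize", "accuracy_max", "consensus")]
print(top, row.names = FALSE)

cat("\nConsensus winners per feature type:\n")
for (ft in unique(ranked$feature_type)) {
  best <- ranked[ranked$feature_type == ft, ][1, ]
  cat(sprintf("  %-10s consensus %.1f (accuracy %.0f%%, %s/%s/%s)\n",
              ft, best$consensus, best$accuracy_max, best$property,
              best$individuality, best$operator))
}
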