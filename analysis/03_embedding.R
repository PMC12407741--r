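#!/usr/bin/env Rscript
# Step 3: summarize feature-pattern similarity across parameter combinations.
#
# For each feature type, pairwise cosine distances between the feature
# vectors of all combinations are turned into a row-adaptive Gaussian
# affinity per scan, averaged across scans then subjects, and
# eigendecomposed; the second and third eigenvectors (u2, u3) give a
# two-dimensional map in which nearby combinations produce similar feature
# patterns.
#
# Output: results/analysis/embedding_<feature>.csv (factor levels + u2/u3).

library(gspfinger)

tables <- readRDS("scratch/tables.rds")

for (ft in names(tables)) {
  tab <- tables[[ft]]$S3
  aff <- suppressWarnings(build_affinity(tab))
  emb <- spectral_embed(aff)
  out <- cbind(aff$combos, round(emb$coords, 6))
  utils::write.csv(out, sprintf("results/analysis/embedding_%s.csv", ft),
                   row.names = FALSE)
  # which factor separates the map the most? correlate u2 with factor levels
  u2 <- emb$coords[, "u2"]
  op_split <- abs(stats::cor(u2, as.numeric(aff$combos$operator == "L_Q")))
  z_split <- abs(stats::cor(u2, as.numeric(aff$combos$zscore)))
  cat(sprintf("%-10s |u2 ~ modularity-vs-rest| = %.2f, |u2 ~ z-scoring| = %.2f\n",
              ft, op_split, z_split))
}
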