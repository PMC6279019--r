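#!/usr/bin/env Rscript
# Stage 6: one-vs-all random-forest classification of group membership
# from genus-level profiles, with SMOTE and downsampling applied inside
# cross-validation only.

suppressMessages(library(cohortsig))

tb <- read_count_table("results/data/cohort_A_qc.tsv")
md <- read_metadata("results/data/cohort_A_qc_metadata.tsv")
g <- setNames(md$ethnicity, md$sample_id)

fe <- prepare_rf_features(tb, g, depth = 10000, seed = 61L)
cat(sprintf("features: %d taxa after presence filter (threshold %d samples)\n",
            ncol(fe$features), fe$presence_threshold))

rows <- list()
for (sampling in c("smote", "down")) {
  rep <- suppressWarnings(rf_one_vs_all(fe, sampling = sampling, k = 10,
                                        seed = 62L, ntree = 300))
  print(rep)
  for (grp in names(rep))
    rows[[paste(sampling, grp)]] <- data.frame(
      sampling = sampling, group = grp, auc = rep[[grp]]$auc,
      sensitivity = rep[[grp]]$sensitivity,
      specificity = rep[[grp]]$specificity,
      precision = rep[[grp]]$precision, oob_error = rep[[grp]]$oob_error)
}
write.table(do.call(rbind, rows), "results/rf_performance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
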