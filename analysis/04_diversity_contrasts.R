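#!/usr/bin/env Rscript
# Stage 4: alpha diversity and intra-/inter-group beta contrasts.
#
# Shannon (and friends) averaged over rarefactions with pairwise Monte
# Carlo t tests; the intra- vs inter-group Bray-Curtis partition in both
# all-pairs and per-individual-mean modes; ubiquity sets and the
# abundance/ubiquity stability regressions per group.

suppressMessages(library(cohortsig))

tb <- read_count_table("results/data/cohort_A_qc.tsv")
md <- read_metadata("results/data/cohort_A_qc_metadata.tsv")
g <- setNames(md$ethnicity, md$sample_id)

for (metric in c("shannon", "observed_otus", "equitability")) {
  al <- alpha_diversity(tb, metric, depth = 1000, n_rarefactions = 10,
                        seed = 41L)
  cmp <- compare_alpha(al, g, n_perm = 999, seed = 42L)
  cat(sprintf("%s: omnibus Kruskal-Wallis H=%.2f p=%.3g\n", metric,
              cmp$omnibus$H, cmp$omnibus$p))
  write.table(cmp$pairwise, sprintf("results/alpha_%s_pairwise.tsv", metric),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

dm <- read_distance_matrix("results/consensus_bray_A.tsv")
for (mode in c("all_pairs", "per_individual_mean")) {
  part <- partition_distances(dm, g, mode)
  res <- compare_distance_sets(part)
  cat(sprintf("[%s] intra mean=%.3f inter mean=%.3f KW p=%.3g\n", mode,
              mean(unlist(part$intra)), mean(unlist(part$inter)),
              res$omnibus$p))
  write.table(res$contrasts, sprintf("results/beta_contrasts_%s.tsv", mode),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

ub <- ubiquitous_otus(tb, g, threshold = 0.5)
cat(sprintf("OTUs ubiquitous in every group: %d; in any group: %d\n",
            length(ub$shared_all), length(ub$shared_any)))
for (grp in names(ub$groups)) {
  gg <- ub$groups[[grp]]
  reg <- gg$regression
  cat(sprintf("  %-24s %3d ubiquitous OTUs, mean A/U=%.4f%s\n", grp,
              length(gg$ubiquitous), gg$mean_au,
              if (!is.null(reg)) sprintf(", regression R2=%.2f p_adj=%.2g",
                                         reg$r2, reg$p_adj) else ""))
  write.table(gg$stats, sprintf("results/ubiquity_%s.tsv",
                                gsub("[^A-Za-z]", "_", grp)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
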