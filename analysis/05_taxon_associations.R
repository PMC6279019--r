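#!/usr/bin/env Rscript
# Stage 5: per-taxon screening, cross-cohort replication, redundancy
# collapsing, pairwise direction calls, covariate regressions, the
# presence-vs-BMI test, and family co-occurrence clustering.

suppressMessages(library(cohortsig))

load_cohort <- function(nm) {
  tb <- read_count_table(sprintf("results/data/cohort_%s_qc.tsv", nm))
  md <- read_metadata(sprintf("results/data/cohort_%s_qc_metadata.tsv", nm))
  list(tb = tb, md = md, g = setNames(md$ethnicity, md$sample_id))
}
A <- load_cohort("A"); B <- load_cohort("B")

ranks <- c("phylum", "class", "order", "family", "genus")
recsA <- associate_taxa(A$tb, A$g, ranks)
recsB <- associate_taxa(B$tb, B$g, ranks)
for (r in ranks)
  write.table(recsA[[r]], sprintf("results/associations_A_%s.tsv", r),
              sep = "\t", quote = FALSE, row.names = FALSE)

ro <- replication_overlap(recsA, recsB, alpha = 0.05)
cat("replication by rank:\n"); print(ro$per_rank, row.names = FALSE)
cat(sprintf("combined overlap: %d taxa significant in both cohorts\n",
            ro$overlap_total))

famA <- collapse_taxonomy(A$tb, "family"); genA <- collapse_taxonomy(A$tb, "genus")
famB <- collapse_taxonomy(B$tb, "family"); genB <- collapse_taxonomy(B$tb, "genus")
ov <- overlap_permutation_null(list(family = famA, genus = genA), A$g,
                               list(family = famB, genus = genB), B$g,
                               n_perm = 1000, seed = 51L)
cat(sprintf("overlap permutation null: observed=%d, p=%.4g\n",
            ov$observed_overlap[["combined"]], ov$perm_p[["combined"]]))

# taxonomically distinct representatives among the replicated taxa
shared <- intersect(ro$significant$A, ro$significant$B)
dist_taxa <- collapse_redundant_taxa(shared, famA, genA, A$g)
cat(sprintf("replicated taxa: %d, taxonomically distinct: %d\n",
            length(shared), sum(dist_taxa$kept)))
write.table(dist_taxa, "results/distinct_replicated_taxa.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

kept <- dist_taxa$taxon[dist_taxa$kept & dist_taxa$rank == "family"]
sa <- pairwise_group_shifts(famA, A$g, taxa = kept)
sb <- pairwise_group_shifts(famB, B$g, taxa = kept)
rs <- replicate_shifts(sa, sb)
cat(sprintf("pairwise shifts on %d distinct families: %d/%d replicated\n",
            length(kept), sum(rs$replicated), nrow(rs)))
write.table(rs, "results/pairwise_shifts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

reg <- abundance_regressions(famA, A$md)
cat(sprintf("covariate regressions: %d/%d families with Bonferroni-significant\n",
            sum(reg$lin_p_bonf < 0.05, na.rm = TRUE), nrow(reg)))
cat("  abundance~ethnicity linear models\n")
write.table(reg, "results/regressions_family_A.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# presence vs BMI for the genus with the most informative carriage split
ubiq <- colMeans(genA$values > 0)
cands <- names(ubiq)[ubiq > 0.2 & ubiq < 0.95]
if (length(cands) > 0) {
  top_tax <- cands[which.min(abs(ubiq[cands] - 0.5))]
  pres <- setNames(genA$values[, top_tax] > 0, rownames(genA$values))
  bmi <- setNames(A$md$bmi, A$md$sample_id)
  pp <- presence_phenotype_test(pres, bmi, A$g)
  cat(sprintf("presence of %s vs BMI (possessors lower): overall p=%.3g\n",
              top_tax, pp$p[pp$scope == "overall"]))
  write.table(pp, "results/presence_bmi.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
} else {
  cat("no genus with intermediate carriage; presence-vs-BMI test skipped\n")
}

ext <- setNames(recsA$family$p_fdr, recsA$family$taxon)
cc <- cooccurrence_clusters(famA, external_assoc_p = ext)
cat(sprintf("co-occurrence: %d cluster(s); sizes: %s; enrichment p=%.3g\n",
            length(cc$clusters),
            paste(lengths(cc$clusters), collapse = ", "),
            if (is.null(cc$enrichment)) NA else cc$enrichment$p))
write.table(round(cc$rho, 4), "results/family_spearman_A.tsv",
            sep = "\t", quote = FALSE)
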