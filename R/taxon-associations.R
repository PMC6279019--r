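#' Per-taxon Kruskal-Wallis screening across groups
#'
#' Tie-corrected Kruskal-Wallis on each taxon's relative abundance across
#' groups, with Benjamini-Hochberg FDR and Bonferroni corrections applied
#' within the call (i.e. within one taxonomic rank and grouping factor),
#' per-group mean abundance and ubiquity, sorted by p.  A taxon constant
#' across all samples (including all-zero) has H = 0, p = 1 and is
#' flagged.  With `exact = TRUE` each p is the exhaustive permutation tail
#' over all distinct label assignments (small n only).
#'
#' @param taxon_table a `taxon_table`.
#' @param groups named group labels (by sample id).
#' @param exact exhaustive-enumeration p-values.
#' @return data.frame: taxon, rank, H, p, p_fdr, p_bonf, flagged, then
#'   `mean_<group>` and `ubiq_<group>` columns; sorted by p.
#' @export
kruskal_by_group <- function(taxon_table, groups, exact = FALSE) {
  vals <- taxon_table$values
  groups <- groups[rownames(vals)]
  if (anyNA(groups)) stop("groups must cover all samples")
  g <- factor(as.character(groups))
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  pre <- kw_rank_precompute(vals)
  kw <- kw_stat_from_ranks(pre, g)
  p <- kw$p
  if (exact) {
    p <- vapply(seq_len(ncol(vals)), function(j)
      kw_exact_p(vals[, j], g), numeric(1))
    p[pre$tie_corr <= 0] <- 1
  }
  flagged <- pre$tie_corr <= 0
  means <- rowsum(vals, g) / as.vector(table(g))
  ubiq <- rowsum((vals > 0) + 0, g) / as.vector(table(g))
  out <- data.frame(taxon = colnames(vals), rank = taxon_table$rank,
                    H = kw$H, p = p,
                    p_fdr = p.adjust(p, "BH"),
                    p_bonf = p.adjust(p, "bonferroni"),
                    flagged = flagged, stringsAsFactors = FALSE)
  for (lev in levels(g)) {
    out[[paste0("mean_", lev)]] <- means[lev, ]
    out[[paste0("ubiq_", lev)]] <- ubiq[lev, ]
  }
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Run the Kruskal-Wallis screen at several taxonomic ranks
#'
#' Convenience wrapper: collapses a count table at each rank and screens
#' each; corrections stay within rank.
#'
#' @param table a [count_table()].
#' @param groups named group labels.
#' @param ranks taxonomic ranks to screen.
#' @return named list of per-rank record data.frames.
#' @export
associate_taxa <- function(table, groups,
                           ranks = c("phylum", "class", "order",
                                     "family", "genus")) {
  setNames(lapply(ranks, function(r)
    kruskal_by_group(collapse_taxonomy(table, r), groups)), ranks)
}

sig_set <- function(records, alpha) records$taxon[records$p_fdr < alpha]

#' Cross-cohort replication overlap
#'
#' Counts identically-labelled taxa FDR-significant in both cohorts,
#' per rank and combined, and tests the observed overlap against a 5%
#' chance expectation with Fisher's exact test (for each cohort: observed
#' overlapping vs non-overlapping significant taxa against the expected
#' 5% split of its significant set).
#'
#' @param recordsA,recordsB per-rank record lists (as from
#'   [associate_taxa()]) or single record data.frames.
#' @param alpha FDR significance level.
#' @return Object of class `replication_result`: `per_rank` (data.frame
#'   rank, n_sig_a, n_sig_b, overlap), `overlap_total`, `significant`
#'   (per-cohort sets), `fisher` (per-cohort test results or NULL).
#' @export
replication_overlap <- function(recordsA, recordsB, alpha = 0.05) {
  if (is.data.frame(recordsA)) recordsA <- list(recordsA)
  if (is.data.frame(recordsB)) recordsB <- list(recordsB)
  ranks <- union(names(recordsA) %||% seq_along(recordsA),
                 names(recordsB) %||% seq_along(recordsB))
  per_rank <- lapply(ranks, function(r) {
    sa <- if (r %in% names(recordsA)) sig_set(recordsA[[r]], alpha) else character(0)
    sb <- if (r %in% names(recordsB)) sig_set(recordsB[[r]], alpha) else character(0)
    data.frame(rank = r, n_sig_a = length(sa), n_sig_b = length(sb),
               overlap = length(intersect(sa, sb)), stringsAsFactors = FALSE)
  })
  per_rank <- do.call(rbind, per_rank)
  sig_a <- unique(unlist(lapply(recordsA, sig_set, alpha)))
  sig_b <- unique(unlist(lapply(recordsB, sig_set, alpha)))
  overlap <- length(intersect(sig_a, sig_b))
  fisher <- NULL
  if (length(sig_a) > 0 && length(sig_b) > 0) {
    fisher <- lapply(list(A = length(sig_a), B = length(sig_b)), function(ns) {
      expected <- max(1L, round(0.05 * ns))
      ft <- fisher.test(matrix(c(overlap, ns - overlap,
                                 expected, ns - expected), nrow = 2))
      list(p = ft$p.value, odds_ratio = unname(ft$estimate),
           expected = expected)
    })
  }
  structure(list(per_rank = per_rank, overlap_total = overlap,
                 significant = list(A = sig_a, B = sig_b),
                 alpha = alpha, fisher = fisher),
            class = "replication_result")
}

#' Permutation null for cross-cohort overlap
#'
#' Each permutation shuffles the group labels independently in both
#' cohorts, recomputes both FDR-significant sets (within each rank) and
#' their identically-labelled overlap.  The permutation p uses the
#' never-zero convention `(1 + #[null >= observed]) / (1 + n_perm)`,
#' reported per rank and for all ranks combined.  Ranks and tie
#' corrections are precomputed once per (cohort, rank), so a permutation
#' costs only group-wise rank sums.
#'
#' @param tablesA,tablesB a `taxon_table` or named list of them (per rank).
#' @param groupsA,groupsB named group labels per cohort.
#' @param alpha FDR level defining significant sets.
#' @param n_perm permutations (>= 1).
#' @param seed RNG seed.
#' @return `replication_result` with added `null_overlap` (matrix perms x
#'   ranks+combined), `perm_p` (named vector), `n_perm`.
#' @export
overlap_permutation_null <- function(tablesA, groupsA, tablesB, groupsB,
                                     alpha = 0.05, n_perm = 1000,
                                     seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(tablesA, "taxon_table")) tablesA <- list(combined = tablesA)
  if (inherits(tablesB, "taxon_table")) tablesB <- list(combined = tablesB)
  ranks <- intersect(names(tablesA), names(tablesB))
  if (length(ranks) == 0) stop("cohorts share no ranks")

  prep <- function(tbl, groups) {
    g <- factor(as.character(groups[rownames(tbl$values)]))
    if (anyNA(g)) stop("groups must cover all samples")
    list(pre = kw_rank_precompute(tbl$values), g = g,
         labels = colnames(tbl$values))
  }
  pa <- lapply(tablesA[ranks], prep, groups = groupsA)
  pb <- lapply(tablesB[ranks], prep, groups = groupsB)

  sig_from <- function(pp, g) {
    p <- kw_stat_from_ranks(pp$pre, g)$p
    pp$labels[p.adjust(p, "BH") < alpha]
  }
  overlap_at <- function(ga_list, gb_list) {
    per <- vapply(ranks, function(r)
      length(intersect(sig_from(pa[[r]], ga_list[[r]]),
                       sig_from(pb[[r]], gb_list[[r]]))), integer(1))
    c(per, combined = sum(per))
  }
  obs <- overlap_at(lapply(pa, `[[`, "g"), lapply(pb, `[[`, "g"))
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      overlap_at(lapply(pa, function(x) sample(x$g)),
                 lapply(pb, function(x) sample(x$g)))
    }, numeric(length(ranks) + 1L)))
  })
  perm_p <- vapply(seq_along(obs), function(k)
    (1 + sum(null[, k] >= obs[k])) / (1 + n_perm), numeric(1))
  names(perm_p) <- names(obs)

  base <- replication_overlap(
    lapply(ranks, function(r) {
      p <- kw_stat_from_ranks(pa[[r]]$pre, pa[[r]]$g)$p
      data.frame(taxon = pa[[r]]$labels, p = p, p_fdr = p.adjust(p, "BH"))
    }) |> setNames(ranks),
    lapply(ranks, function(r) {
      p <- kw_stat_from_ranks(pb[[r]]$pre, pb[[r]]$g)$p
      data.frame(taxon = pb[[r]]$labels, p = p, p_fdr = p.adjust(p, "BH"))
    }) |> setNames(ranks),
    alpha = alpha)
  base$null_overlap <- null
  base$perm_p <- perm_p
  base$observed_overlap <- obs
  base$n_perm <- n_perm
  base
}

#' Collapse taxonomically redundant family/genus pairs
#'
#' A significant genus whose abundance accounts for at least `threshold`
#' (default 82%) of its parent family's abundance in every group carries
#' the same signal as the family; only one representative is kept -- the
#' genus if classified, the family if the genus is unclassified (`g__`).
#'
#' @param taxa character vector of candidate taxon labels (family- and
#'   genus-level collapsed labels, as produced by [collapse_taxonomy()]).
#' @param family_table,genus_table `taxon_table`s at family and genus rank.
#' @param groups named group labels.
#' @param threshold minimum abundance fraction, in every group, for a
#'   genus to be deemed redundant with its family.
#' @return data.frame: taxon, rank, kept (logical), redundant_with.
#' @export
collapse_redundant_taxa <- function(taxa, family_table, genus_table, groups,
                                    threshold = 0.82) {
  if (!identical(rownames(genus_table$values), rownames(family_table$values)))
    stop("family and genus tables must cover the same samples")
  groups <- as.character(groups[rownames(family_table$values)])
  sizes <- as.vector(table(groups))
  fam_means <- rowsum(family_table$values, groups) / sizes
  gen_means <- rowsum(genus_table$values, groups) / sizes

  fams <- taxa[taxa %in% colnames(family_table$values)]
  gens <- taxa[taxa %in% colnames(genus_table$values)]
  out <- data.frame(taxon = taxa,
                    rank = ifelse(taxa %in% fams, "family",
                                  ifelse(taxa %in% gens, "genus", "other")),
                    kept = TRUE, redundant_with = NA_character_,
                    stringsAsFactors = FALSE)
  for (gn in gens) {
    parent <- sub("; g__.*$", "", gn)
    fam_hit <- fams[fams == parent]
    if (length(fam_hit) != 1) next
    ratio <- gen_means[, gn] / pmax(fam_means[, fam_hit], 1e-300)
    if (all(ratio >= threshold)) {
      if (label_is_classified(gn, "genus")) {
        out$kept[out$taxon == fam_hit] <- FALSE
        out$redundant_with[out$taxon == fam_hit] <- gn
      } else {
        out$kept[out$taxon == gn] <- FALSE
        out$redundant_with[out$taxon == gn] <- fam_hit
      }
    }
  }
  out
}

#' Pairwise group shifts for selected taxa
#'
#' For each taxon and each pair of groups: a two-sided Mann-Whitney U on
#' relative abundance over ALL individuals (zeros are data), Bonferroni
#' corrected within taxon for the number of pairs (6 at four groups);
#' direction of change in abundance (mean difference, second group of the
#' sorted pair relative to the first) and of ubiquity.
#'
#' @param taxon_table a `taxon_table`.
#' @param groups named group labels.
#' @param taxa taxa to test (default all columns).
#' @return data.frame: taxon, group_a, group_b, U, p, p_bonf,
#'   direction_abundance, direction_ubiquity.
#' @export
pairwise_group_shifts <- function(taxon_table, groups, taxa = NULL) {
  vals <- taxon_table$values
  groups <- as.character(groups[rownames(vals)])
  taxa <- taxa %||% colnames(vals)
  taxa <- intersect(taxa, colnames(vals))
  glev <- sort(unique(groups))
  pairs <- combn(glev, 2, simplify = FALSE)
  rows <- list()
  for (tx in taxa) {
    x <- vals[, tx]
    for (pr in pairs) {
      xa <- x[groups == pr[1]]; xb <- x[groups == pr[2]]
      w <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE, correct = FALSE))
      p <- if (is.na(w$p.value)) 1 else w$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, group_a = pr[1], group_b = pr[2],
        U = unname(w$statistic), p = p,
        p_bonf = min(1, p * length(pairs)),
        direction_abundance = ifelse(mean(xb) >= mean(xa), "up", "down"),
        direction_ubiquity = ifelse(mean(xb > 0) >= mean(xa > 0), "up", "down"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Replication of pairwise shifts across two cohorts
#'
#' A shift replicates when it is Bonferroni-significant in both cohorts
#' with the same abundance direction.
#'
#' @param shiftsA,shiftsB outputs of [pairwise_group_shifts()] for the two
#'   cohorts (matched on taxon and group pair).
#' @param alpha significance level on the Bonferroni-corrected p.
#' @return merged data.frame with `replicated` flag.
#' @export
replicate_shifts <- function(shiftsA, shiftsB, alpha = 0.05) {
  key <- c("taxon", "group_a", "group_b")
  m <- merge(shiftsA, shiftsB, by = key, suffixes = c("_a", "_b"))
  m$replicated <- m$p_bonf_a < alpha & m$p_bonf_b < alpha &
    m$direction_abundance_a == m$direction_abundance_b
  m
}

#' Linear and logistic covariate regressions per taxon
#'
#' For each taxon: (i) linear regression of log10 relative abundance among
#' possessors (strictly positive abundance), and (ii) logistic regression
#' of presence/absence over all individuals.  Each is fitted with the
#' grouping factor alone (model 1) and with age, sex and BMI added
#' (model 2); the factor is dummy coded with the largest group as
#' reference.  Overall model p is the F test (linear) or likelihood-ratio
#' test against the null model (logistic); per-term p-values come from
#' `drop1`.  Bonferroni correction is across taxa.
#'
#' @param taxon_table a `taxon_table`.
#' @param metadata data.frame with `sample_id`, `ethnicity`, `age`, `sex`,
#'   `bmi`.
#' @param group_col metadata column holding the grouping factor.
#' @param covariates covariate columns for model 2.
#' @param min_possessors minimum possessors for the linear fit.
#' @return data.frame, one row per taxon, with model p-values, fit
#'   statistics, per-term p-values and skip flags.
#' @export
abundance_regressions <- function(taxon_table, metadata,
                                  group_col = "ethnicity",
                                  covariates = c("age", "sex", "bmi"),
                                  min_possessors = 10) {
  vals <- taxon_table$values
  md <- metadata[match(rownames(vals), metadata$sample_id), , drop = FALSE]
  grp <- factor(md[[group_col]])
  grp <- relevel(grp, ref = names(which.max(table(grp))))
  rows <- list()
  for (tx in colnames(vals)) {
    x <- vals[, tx]
    pres <- x > 0
    row <- list(taxon = tx, n_possessors = sum(pres),
                lin_p = NA, lin_p_full = NA, lin_r2 = NA, lin_skipped = TRUE,
                log_p = NA, log_p_full = NA, log_skipped = TRUE)
    term_ps <- setNames(rep(NA_real_, length(covariates) + 1L),
                        c(group_col, covariates))
    if (sum(pres) >= min_possessors &&
        length(unique(grp[pres])) >= 2) {
      d <- data.frame(y = log10(x[pres]), grp = droplevels(grp[pres]),
                      md[pres, covariates, drop = FALSE])
      m1 <- lm(y ~ grp, data = d)
      m2 <- lm(as.formula(paste("y ~ grp +",
                                paste(covariates, collapse = " + "))), data = d)
      fs1 <- suppressWarnings(summary(m1))$fstatistic  # exact fits are legal
      fs2 <- suppressWarnings(summary(m2))$fstatistic
      row$lin_p <- unname(stats::pf(fs1[1], fs1[2], fs1[3], lower.tail = FALSE))
      row$lin_p_full <- unname(stats::pf(fs2[1], fs2[2], fs2[3],
                                         lower.tail = FALSE))
      row$lin_r2 <- suppressWarnings(summary(m2))$r.squared
      row$lin_skipped <- FALSE
      dr <- suppressWarnings(drop1(m2, test = "F"))
      term_ps[group_col] <- dr["grp", "Pr(>F)"]
      for (cv in covariates)
        if (cv %in% rownames(dr)) term_ps[cv] <- dr[cv, "Pr(>F)"]
    }
    if (any(pres) && !all(pres)) {
      d <- data.frame(y = as.numeric(pres), grp = grp,
                      md[, covariates, drop = FALSE])
      # complete separation is expected under strong planted effects; the
      # LR test against the null model remains usable
      g1 <- suppressWarnings(glm(y ~ grp, data = d, family = binomial()))
      g2 <- suppressWarnings(glm(as.formula(paste("y ~ grp +",
                                 paste(covariates, collapse = " + "))),
                data = d, family = binomial()))
      g0 <- glm(y ~ 1, data = d, family = binomial())
      row$log_p <- anova(g0, g1, test = "Chisq")$`Pr(>Chi)`[2]
      row$log_p_full <- anova(g0, g2, test = "Chisq")$`Pr(>Chi)`[2]
      row$log_skipped <- FALSE
    }
    for (nm in names(term_ps)) row[[paste0("term_p_", nm)]] <- term_ps[[nm]]
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$lin_p_bonf <- pmin(1, out$lin_p * nrow(out))
  out$log_p_bonf <- pmin(1, out$log_p * nrow(out))
  out
}

#' Presence-phenotype one-tailed tests
#'
#' Tests whether individuals carrying a taxon have a LOWER value of a
#' continuous phenotype (the motivating case: Christensenellaceae carriers
#' have lower BMI), with a one-tailed Mann-Whitney U, overall and within
#' each group.  Groups with an empty presence class are skipped; a
#' constant phenotype yields p = 1 with a flag.
#'
#' @param presence logical/0-1 vector named by sample id.
#' @param phenotype numeric vector named by sample id.
#' @param groups named group labels.
#' @param alternative passed to [wilcox.test()]; `"less"` means possessors
#'   lower.
#' @return data.frame: scope ("overall" or group), n_with, n_without,
#'   mean_with, mean_without, U, p, skipped.
#' @export
presence_phenotype_test <- function(presence, phenotype, groups = NULL,
                                    alternative = "less") {
  ids <- names(presence)
  phenotype <- phenotype[ids]
  presence <- as.logical(presence)
  one <- function(scope, sel) {
    w <- presence[sel] & !is.na(phenotype[sel])
    wo <- !presence[sel] & !is.na(phenotype[sel])
    x <- phenotype[sel][w]; y <- phenotype[sel][wo]
    if (length(x) == 0 || length(y) == 0)
      return(data.frame(scope = scope, n_with = length(x),
                        n_without = length(y), mean_with = NA,
                        mean_without = NA, U = NA, p = NA, skipped = TRUE))
    if (length(unique(c(x, y))) < 2)
      return(data.frame(scope = scope, n_with = length(x),
                        n_without = length(y), mean_with = mean(x),
                        mean_without = mean(y), U = NA, p = 1, skipped = TRUE))
    wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                       exact = FALSE, correct = FALSE))
    data.frame(scope = scope, n_with = length(x), n_without = length(y),
               mean_with = mean(x), mean_without = mean(y),
               U = unname(wt$statistic), p = wt$p.value, skipped = FALSE)
  }
  out <- one("overall", rep(TRUE, length(ids)))
  if (!is.null(groups)) {
    groups <- as.character(groups[ids])
    for (g in sort(unique(groups)))
      out <- rbind(out, one(g, groups == g))
  }
  out
}
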