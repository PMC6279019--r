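#' Partition pairwise distances into intra- and inter-group sets
#'
#' `all_pairs` mode bins every condensed distance by the (group, group)
#' pair it connects.  `per_individual_mean` mode collapses each
#' individual's distances to each comparison group into a single mean
#' (self excluded for the own group), which guards against pseudo-inflation
#' from the quadratic growth of pair counts.
#'
#' @param dm a `distance_matrix`.
#' @param groups named group labels (by sample id).
#' @param mode `"all_pairs"` or `"per_individual_mean"`.
#' @return Object of class `distance_partition`: `intra` (named list of
#'   per-group value vectors), `inter` (named list per group pair,
#'   `"A|B"`), `mode`, `flagged` (groups of size 1, empty intra set).
#' @export
partition_distances <- function(dm, groups,
                                mode = c("all_pairs", "per_individual_mean")) {
  mode <- match.arg(mode)
  groups <- as.character(groups[dm$sample_ids])
  if (anyNA(groups)) stop("groups must cover all samples")
  glev <- sort(unique(groups))
  n <- length(groups)
  v <- dm$values
  intra <- setNames(vector("list", length(glev)), glev)
  pairs <- if (length(glev) >= 2) combn(glev, 2, simplify = FALSE) else list()
  inter <- setNames(vector("list", length(pairs)),
                    vapply(pairs, paste, character(1), collapse = "|"))
  if (mode == "all_pairs") {
    idx <- pair_indices(n)
    d <- condense(v)
    gi <- groups[idx[, "i"]]; gj <- groups[idx[, "j"]]
    for (g in glev) intra[[g]] <- d[gi == g & gj == g]
    for (k in seq_along(pairs)) {
      a <- pairs[[k]][1]; b <- pairs[[k]][2]
      inter[[k]] <- d[(gi == a & gj == b) | (gi == b & gj == a)]
    }
  } else {
    for (g in glev) {
      members <- which(groups == g)
      if (length(members) < 2) { intra[[g]] <- numeric(0); next }
      intra[[g]] <- vapply(members, function(i)
        mean(v[i, setdiff(members, i)]), numeric(1))
    }
    for (k in seq_along(pairs)) {
      a <- pairs[[k]][1]; b <- pairs[[k]][2]
      ia <- which(groups == a); ib <- which(groups == b)
      inter[[k]] <- c(vapply(ia, function(i) mean(v[i, ib]), numeric(1)),
                      vapply(ib, function(i) mean(v[i, ia]), numeric(1)))
    }
  }
  flagged <- glev[vapply(intra, length, integer(1)) == 0]
  structure(list(intra = intra, inter = inter, mode = mode,
                 flagged = flagged),
            class = "distance_partition")
}

#' Test intra- vs inter-group distance sets
#'
#' Kruskal-Wallis across the intra-group sets; two-sided Mann-Whitney U
#' for each intra-intra pair and for each intra set against the pooled
#' inter-group distances.  Bonferroni correction is applied within each
#' contrast family (the C(G,2) intra-intra tests and the G intra-inter
#' tests).
#'
#' @param partition a `distance_partition`.
#' @return list with `omnibus` (H, p across intra sets) and `contrasts`
#'   (data.frame: type, set_a, set_b, U, p, p_bonf, skipped).
#' @export
compare_distance_sets <- function(partition) {
  stopifnot(inherits(partition, "distance_partition"))
  intra <- partition$intra[vapply(partition$intra, length, integer(1)) > 0]
  if (length(intra) < 2) stop("need at least 2 non-empty intra sets")
  pooled_inter <- unlist(partition$inter, use.names = FALSE)
  kw <- kruskal.test(unlist(intra),
                     factor(rep(names(intra), lengths(intra))))
  mwu <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) return(c(NA, NA))
    w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    c(unname(w$statistic), w$p.value)
  }
  ii_pairs <- combn(names(intra), 2, simplify = FALSE)
  rows <- lapply(ii_pairs, function(pr) {
    r <- mwu(intra[[pr[1]]], intra[[pr[2]]])
    data.frame(type = "intra_intra", set_a = pr[1], set_b = pr[2],
               U = r[1], p = r[2],
               p_bonf = min(1, r[2] * length(ii_pairs)),
               skipped = anyNA(r))
  })
  rows2 <- lapply(names(intra), function(g) {
    r <- mwu(intra[[g]], pooled_inter)
    data.frame(type = "intra_inter", set_a = g, set_b = "inter(all)",
               U = r[1], p = r[2],
               p_bonf = min(1, r[2] * length(intra)),
               skipped = anyNA(r))
  })
  list(omnibus = list(H = unname(kw$statistic), p = kw$p.value),
       contrasts = do.call(rbind, c(rows, rows2)))
}

#' Ubiquitous OTUs and abundance/ubiquity stability statistics
#'
#' Per group: OTUs detected (nonzero) in at least `threshold` of the
#' group's samples (inclusive, so exactly 50% qualifies at the default);
#' per-OTU mean relative abundance over ALL of the group's samples (zeros
#' included, unless `possessors_only`); the A/U ratio
#' (mean abundance / ubiquity, lower = more stable); and an OLS regression
#' of log10 mean abundance on ubiquity over the qualifying OTUs with
#' HC3 heteroscedasticity-robust standard errors, Bonferroni adjusted for
#' the number of groups.
#'
#' @param table a [count_table()].
#' @param groups named group labels (by sample id).
#' @param threshold ubiquity cutoff in `(0, 1]`.
#' @param possessors_only average abundance over possessing samples only
#'   (the default averages over all group samples).
#' @return Object of class `ubiquity_summary`: per-group `stats`
#'   (data.frame otu, mean_abundance, ubiquity, au), `ubiquitous` (OTU id
#'   sets), `regression` (slope, intercept, r2, p, p_adj), `mean_au`;
#'   plus `shared_all` (OTUs ubiquitous in every group) and `shared_any`.
#' @export
ubiquitous_otus <- function(table, groups, threshold = 0.5,
                            possessors_only = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  groups <- as.character(groups[table$sample_ids])
  rel <- table$counts / rowSums(table$counts)
  glev <- sort(unique(groups))
  per_group <- list()
  for (g in glev) {
    rows <- groups == g
    sub <- rel[rows, , drop = FALSE]
    ubiq <- colMeans(sub > 0)
    mean_ab <- if (possessors_only) {
      vapply(seq_len(ncol(sub)), function(j) {
        x <- sub[sub[, j] > 0, j]
        if (length(x) == 0) 0 else mean(x)
      }, numeric(1))
    } else colMeans(sub)
    stats <- data.frame(otu = colnames(sub), mean_abundance = mean_ab,
                        ubiquity = ubiq,
                        au = ifelse(ubiq > 0, mean_ab / ubiq, NA),
                        stringsAsFactors = FALSE)
    qualifying <- stats$otu[stats$ubiquity >= threshold]
    reg <- NULL
    if (length(qualifying) >= 3) {
      sub_stats <- stats[stats$otu %in% qualifying &
                           stats$mean_abundance > 0, ]
      fit <- lm(log10(mean_abundance) ~ ubiquity, data = sub_stats)
      ct <- suppressWarnings(
        lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC3")))
      reg <- list(slope = unname(coef(fit)[2]),
                  intercept = unname(coef(fit)[1]),
                  r2 = suppressWarnings(summary(fit))$r.squared,
                  p = ct["ubiquity", "Pr(>|t|)"],
                  p_adj = min(1, ct["ubiquity", "Pr(>|t|)"] * length(glev)))
    }
    per_group[[g]] <- list(stats = stats, ubiquitous = qualifying,
                           regression = reg,
                           mean_au = mean(stats$au[stats$otu %in% qualifying]))
  }
  sets <- lapply(per_group, `[[`, "ubiquitous")
  structure(list(groups = per_group, threshold = threshold,
                 shared_all = Reduce(intersect, sets),
                 shared_any = Reduce(union, sets)),
            class = "ubiquity_summary")
}

#' Family co-occurrence clustering
#'
#' Pairwise Spearman correlations between family relative abundances,
#' Bonferroni-masked over all family pairs.  Clusters are an explicit
#' formalisation of the visual clustermap reading: average-linkage
#' hierarchical clustering on `1 - rho` (non-significant edges treated as
#' rho = 0), cut at `1 - rho_threshold`, keeping groups with at least
#' `min_cluster_size` members.  A non-member family with at least three
#' significant positive links into a cluster is flagged
#' "cluster-associated".  Enrichment of external group association among
#' cluster members is a one-sided Mann-Whitney U on the supplied p-values
#' (members lower).
#'
#' @param family_table a `taxon_table` at family rank.
#' @param external_assoc_p named p-values (by family label) from an
#'   external association screen; families missing from it are excluded
#'   from the enrichment test only.
#' @param alpha significance level for the Bonferroni mask.
#' @param rho_threshold minimum correlation for cluster edges.
#' @param min_cluster_size minimum cluster size.
#' @return Object of class `cooccurrence_clusters`: `rho` and `p_bonf`
#'   matrices, `mask` (significant after correction), `clusters` (named
#'   list of member vectors), `cluster_associated` (per cluster),
#'   `enrichment` (U, p), `excluded` (constant families).
#' @export
cooccurrence_clusters <- function(family_table, external_assoc_p = NULL,
                                  alpha = 0.05, rho_threshold = 0.3,
                                  min_cluster_size = 3) {
  vals <- family_table$values
  const <- apply(vals, 2L, function(x) length(unique(x)) < 2)
  if (any(const)) {
    warning("constant-abundance family(ies) excluded: ",
            paste(colnames(vals)[const], collapse = ", "))
    vals <- vals[, !const, drop = FALSE]
  }
  m <- ncol(vals)
  if (m < 3) stop("need at least 3 non-constant families")
  rho <- cor(vals, method = "spearman")
  pmat <- matrix(1, m, m, dimnames = dimnames(rho))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ct <- suppressWarnings(cor.test(vals[, i], vals[, j],
                                    method = "spearman", exact = FALSE))
    pmat[i, j] <- pmat[j, i] <- ct$p.value
  }
  n_tests <- m * (m - 1) / 2
  p_bonf <- pmat * n_tests
  p_bonf[p_bonf > 1] <- 1
  diag(p_bonf) <- 0
  mask <- p_bonf <= alpha
  diag(mask) <- TRUE

  edge_rho <- rho
  edge_rho[!mask] <- 0
  d <- as.dist(1 - edge_rho)
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, h = 1 - rho_threshold)
  tab <- table(grp)
  keep_ids <- names(tab)[tab >= min_cluster_size]
  clusters <- lapply(keep_ids, function(k) names(grp)[grp == k])
  if (length(clusters) > 0)
    names(clusters) <- paste0("cluster", seq_along(clusters))

  cluster_associated <- lapply(clusters, function(members) {
    others <- setdiff(colnames(vals), members)
    links <- vapply(others, function(f)
      sum(mask[f, members] & rho[f, members] > 0), integer(1))
    names(links)[links >= 3]
  })

  enrichment <- NULL
  if (!is.null(external_assoc_p) && length(clusters) > 0) {
    members <- unique(unlist(clusters))
    in_p <- external_assoc_p[intersect(members, names(external_assoc_p))]
    out_p <- external_assoc_p[intersect(setdiff(colnames(vals), members),
                                        names(external_assoc_p))]
    if (length(in_p) > 0 && length(out_p) > 0) {
      w <- suppressWarnings(wilcox.test(in_p, out_p, alternative = "less",
                                        exact = FALSE))
      enrichment <- list(U = unname(w$statistic), p = w$p.value)
    }
  }
  structure(list(rho = rho, p_bonf = p_bonf, mask = mask,
                 clusters = clusters,
                 cluster_associated = cluster_associated,
                 enrichment = enrichment,
                 excluded = colnames(family_table$values)[const]),
            class = "cooccurrence_clusters")
}
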