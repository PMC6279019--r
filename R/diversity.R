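#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via \code{vegan::rrarefy}); samples whose total falls below `depth` are
#' dropped and reported in a message.
#'
#' @param table a [count_table()].
#' @param depth target depth (>= 1).
#' @param seed RNG seed.
#' @return a rarefied [count_table()].
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "count_table"), depth >= 1)
  totals <- rowSums(table$counts)
  keep <- table$sample_ids[totals >= depth]
  if (length(keep) == 0)
    stop("no sample reaches depth ", depth, "; rarefied table would be empty")
  if (length(keep) < length(table$sample_ids))
    message(length(table$sample_ids) - length(keep),
            " sample(s) below depth ", depth, " dropped")
  sub <- table$counts[keep, , drop = FALSE]
  # vegan::rrarefy emits an informational warning on very small toy tables;
  # integer counts are already enforced by the count_table invariants
  rar <- with_seed(seed, suppressWarnings(vegan::rrarefy(sub, depth)))
  storage.mode(rar) <- "integer"
  count_table(rar, table$taxonomy)
}

alpha_metric_fun <- function(metric, chao1_classical = FALSE) {
  switch(metric,
    shannon = function(x) {
      p <- x[x > 0] / sum(x)
      -sum(p * log2(p))
    },
    simpson = function(x) {
      p <- x / sum(x)
      1 - sum(p^2)
    },
    equitability = function(x) {
      s <- sum(x > 0)
      if (s <= 1) return(NA_real_)
      p <- x[x > 0] / sum(x)
      -sum(p * log2(p)) / log2(s)
    },
    observed_otus = function(x) sum(x > 0),
    chao1 = function(x) {
      s <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      if (chao1_classical) {
        if (f2 == 0) return(s + f1 * (f1 - 1) / 2)  # classical fallback
        s + f1^2 / (2 * f2)
      } else {
        s + f1 * (f1 - 1) / (2 * (f2 + 1))          # bias-corrected
      }
    },
    stop("unknown alpha metric: ", metric))
}

#' Alpha diversity averaged over rarefactions
#'
#' Computes the metric on each of `n_rarefactions` independently rarefied
#' tables and averages per sample.  Shannon is in bits (log base 2, the
#' convention of the QIIME-era scripts this mirrors); Equitability is
#' Shannon / log2(observed OTUs); Simpson is 1 - sum p^2; Chao1 is the
#' bias-corrected form `S + F1(F1-1) / (2(F2+1))` unless
#' `chao1_classical = TRUE`.
#'
#' @param table a [count_table()].
#' @param metric one of `"shannon"`, `"simpson"`, `"equitability"`,
#'   `"chao1"`, `"observed_otus"`.
#' @param depth rarefaction depth.
#' @param n_rarefactions rarefied tables to average over.
#' @param seed RNG seed.
#' @param chao1_classical use the classical `S + F1^2/(2 F2)` Chao1.
#' @return Object of class `alpha_result`: per-sample `values`, `metric`,
#'   `depth`, `n_rarefactions`.
#' @export
alpha_diversity <- function(table, metric, depth, n_rarefactions = 10,
                            seed = NULL, chao1_classical = FALSE) {
  metric <- match.arg(metric, c("shannon", "simpson", "equitability",
                                "chao1", "observed_otus"))
  f <- alpha_metric_fun(metric, chao1_classical)
  seeds <- derive_seeds(seed, n_rarefactions)
  acc <- NULL
  for (r in seq_len(n_rarefactions)) {
    rt <- suppressMessages(rarefy(table, depth, seed = seeds[[r]]))
    vals <- apply(rt$counts, 1L, f)
    if (is.null(acc)) acc <- matrix(NA_real_, n_rarefactions, length(vals),
                                    dimnames = list(NULL, names(vals)))
    acc[r, names(vals)] <- vals
  }
  structure(list(values = colMeans(acc), metric = metric, depth = depth,
                 n_rarefactions = n_rarefactions),
            class = "alpha_result")
}

#' Compare alpha diversity between groups
#'
#' Pairwise nonparametric t tests: the Welch t statistic with a Monte Carlo
#' permutation p (group labels shuffled, two-sided), Bonferroni corrected
#' over the number of pairs; plus an omnibus Kruskal-Wallis test.  With
#' `exhaustive = TRUE` the permutation distribution is enumerated over all
#' distinct label assignments instead of sampled.
#'
#' @param values an `alpha_result` or a named numeric vector (by sample).
#' @param groups named group labels (by sample id).
#' @param n_perm Monte Carlo permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all label assignments (small n only).
#' @return list with `pairwise` (data.frame pair, t, p, p_bonf, skipped)
#'   and `omnibus` (Kruskal-Wallis H and p).
#' @export
compare_alpha <- function(values, groups, n_perm = 999, seed = NULL,
                          exhaustive = FALSE) {
  if (inherits(values, "alpha_result")) values <- values$values
  groups <- groups[names(values)]
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need at least 2 groups")
  t_stat <- function(x, g, a, b) {
    xa <- x[g == a]; xb <- x[g == b]
    va <- var(xa) / length(xa); vb <- var(xb) / length(xb)
    if (va + vb == 0) return(0)
    (mean(xa) - mean(xb)) / sqrt(va + vb)
  }
  pairs <- combn(glev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    if (sum(groups == pr[1]) < 2 || sum(groups == pr[2]) < 2)
      return(data.frame(group_a = pr[1], group_b = pr[2], t = NA, p = NA,
                        p_bonf = NA, skipped = TRUE))
    x <- values[sel]; g <- groups[sel]
    obs <- t_stat(x, g, pr[1], pr[2])
    if (exhaustive) {
      perms <- multiset_permutations(g)
      stats <- apply(perms, 2L, function(gp) t_stat(x, gp, pr[1], pr[2]))
      p <- mean(abs(stats) >= abs(obs) - 1e-12)
    } else {
      hits <- with_seed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
          gp <- sample(g)
          abs(t_stat(x, gp, pr[1], pr[2])) >= abs(obs) - 1e-12
        }, logical(1)))
      })
      p <- (1 + hits) / (1 + n_perm)
    }
    data.frame(group_a = pr[1], group_b = pr[2], t = obs, p = p,
               p_bonf = min(1, p * length(pairs)), skipped = FALSE)
  })
  kw <- kruskal.test(values, factor(groups))
  list(pairwise = do.call(rbind, rows),
       omnibus = list(H = unname(kw$statistic), p = kw$p.value))
}

#' Non-phylogenetic beta diversity
#'
#' Bray-Curtis (`sum |u-v| / sum (u+v)` on counts), binary Jaccard
#' (1 - intersection/union of presence sets), Canberra (normalised) or
#' Euclidean distances, via \code{vegan::vegdist}.
#'
#' @param table a [count_table()] (or bare counts matrix).
#' @param metric one of `"bray_curtis"`, `"jaccard_binary"`, `"canberra"`,
#'   `"euclidean"`.
#' @return a `distance_matrix`: labelled symmetric matrix with zero
#'   diagonal, plus `metric` and `provenance` fields.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "jaccard_binary",
                                             "canberra", "euclidean")) {
  metric <- match.arg(metric)
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero) > 0)
    stop("sample(s) with all-zero counts: ", paste(zero, collapse = ", "))
  d <- switch(metric,
    bray_curtis = vegan::vegdist(counts, method = "bray"),
    jaccard_binary = vegan::vegdist(counts, method = "jaccard", binary = TRUE),
    canberra = vegan::vegdist(counts, method = "canberra"),
    euclidean = dist(counts))
  distance_matrix(as.matrix(d), metric = metric, provenance = "direct")
}

#' Construct a labelled distance matrix
#'
#' @param values symmetric matrix with dimnames, zero diagonal.
#' @param metric metric name.
#' @param provenance `"direct"` or a list `(depth, n_rarefactions, seed)`.
#' @export
distance_matrix <- function(values, metric = "unknown", provenance = "direct") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            !is.null(rownames(values)))
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix not symmetric")
  if (max(abs(diag(values))) > 1e-12) stop("distance matrix diagonal not zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(list(values = values, sample_ids = rownames(values),
                 metric = metric, provenance = provenance),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", x$metric, ", ", length(x$sample_ids),
      " samples\n", sep = "")
  invisible(x)
}

subset_distance_matrix <- function(dm, samples) {
  distance_matrix(dm$values[samples, samples, drop = FALSE],
                  metric = dm$metric, provenance = dm$provenance)
}

#' Write / read a distance matrix as labelled square TSV
#' @param dm a `distance_matrix`.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = dm$sample_ids, dm$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  distance_matrix(m)
}

#' Consensus beta-diversity matrix over rarefactions
#'
#' Element-wise mean of `n_rarefactions` rarefied distance matrices (the
#' averaging that stabilises distinguishability tests against rarefaction
#' noise).  Samples below `depth` are dropped up front so every rarefied
#' matrix covers the same sample set.
#'
#' @inheritParams rarefy
#' @inheritParams beta_diversity
#' @param n_rarefactions number of rarefied matrices averaged.
#' @return a `distance_matrix` with rarefaction provenance.
#' @export
consensus_distance <- function(table, metric = "bray_curtis", depth,
                               n_rarefactions = 100, seed = NULL) {
  stopifnot(n_rarefactions >= 1)
  totals <- rowSums(table$counts)
  keep <- table$sample_ids[totals >= depth]
  if (length(keep) == 0) stop("no sample reaches depth ", depth)
  base <- subset_count_table(table, samples = keep)
  seeds <- derive_seeds(seed, n_rarefactions)
  acc <- 0
  for (r in seq_len(n_rarefactions)) {
    rt <- suppressMessages(rarefy(base, depth, seed = seeds[[r]]))
    acc <- acc + beta_diversity(rt, metric)$values
  }
  distance_matrix(acc / n_rarefactions, metric = metric,
                  provenance = list(depth = depth,
                                    n_rarefactions = n_rarefactions,
                                    seed = seed))
}
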