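# Fixtures and independent oracles used across the suite.  The oracles
# deliberately avoid the package's own permutation machinery: label
# arrangements are enumerated here by brute force over utils::combn /
# full recursion, and test statistics are recomputed from their textbook
# definitions (or via the corresponding stats:: test).

# --- fixtures ----------------------------------------------------------

tiny_count_table <- function() {
  counts <- matrix(c(5L, 0L, 3L, 12L,
                     2L, 7L, 0L, 11L,
                     9L, 1L, 4L, 6L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("o1", "o2", "o3", "o4")))
  tax <- c(o1 = "k__Bacteria; p__P1; c__C1; o__O1; f__FX; g__GA",
           o2 = "k__Bacteria; p__P1; c__C1; o__O1; f__FX; g__GB",
           o3 = "k__Bacteria; p__P1; c__C1; o__O1; f__FX; g__",
           o4 = "k__Bacteria; p__P2; c__C2; o__O2; f__FY; g__GC")
  count_table(counts, tax)
}

qc_metadata <- function(ids) {
  data.frame(sample_id = ids,
             ethnicity = "Caucasian", sex = "female",
             age = 30, bmi = 25, body_site = "fecal", country = "USA",
             stringsAsFactors = FALSE)
}

# distance matrix from explicit coordinates (euclidean)
dm_from_points <- function(x, ids = NULL) {
  x <- as.matrix(x)
  ids <- ids %||% sprintf("p%02d", seq_len(nrow(x)))
  rownames(x) <- ids
  m <- as.matrix(dist(x))
  distance_matrix(m, metric = "euclidean")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- enumeration oracles ----------------------------------------------

# every arrangement of `labels` over the samples, by full recursion with
# de-duplication (independent of the package's generator)
oracle_all_assignments <- function(labels) {
  n <- length(labels)
  perms <- matrix(NA_character_, nrow = n, ncol = 0)
  rec <- function(remaining, acc) {
    if (length(remaining) == 0) {
      perms <<- cbind(perms, acc)
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      rec(remaining[-i], c(acc, v))
    }
  }
  rec(labels, character(0))
  perms
}

# exact two-sided tail of a statistic over all label assignments
oracle_exact_tail <- function(x, labels, stat_fun, two_sided = FALSE) {
  perms <- oracle_all_assignments(labels)
  obs <- stat_fun(x, labels)
  stats <- apply(perms, 2L, function(g) stat_fun(x, g))
  if (two_sided) mean(abs(stats) >= abs(obs) - 1e-12)
  else mean(stats >= obs - 1e-12)
}

# textbook ANOSIM R for the oracle (recomputed from scratch)
oracle_anosim_R <- function(dmat, g) {
  n <- length(g)
  d <- dmat[lower.tri(dmat)]
  r <- rank(d)
  within <- outer(g, g, "==")[lower.tri(dmat)]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# Kruskal-Wallis H via stats::kruskal.test (independent implementation)
oracle_kw_H <- function(x, g) unname(kruskal.test(x, factor(g))$statistic)

# Welch t statistic, textbook form
oracle_t <- function(x, g, a, b) {
  xa <- x[g == a]; xb <- x[g == b]
  (mean(xa) - mean(xb)) / sqrt(var(xa) / length(xa) + var(xb) / length(xb))
}

# Mann-Whitney U exact tail by enumerating subsets (combn)
oracle_mwu_exact_p <- function(x, y, two_sided = TRUE) {
  nx <- length(x); pool <- c(x, y)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_of(seq_len(nx))
  all_u <- apply(combn(length(pool), nx), 2L, u_of)
  mu <- nx * (length(pool) - nx) / 2
  if (two_sided) mean(abs(all_u - mu) >= abs(obs - mu) - 1e-12)
  else mean(all_u >= obs - 1e-12)
}
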