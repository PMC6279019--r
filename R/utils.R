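# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing randomness in the package funnels through this so that a
# given seed yields byte-identical output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All distinct arrangements of a label multiset, as a matrix with one
# arrangement per column.  Used for exhaustive permutation tests; the count
# is the multinomial coefficient, capped to keep enumeration honest.
multiset_permutations <- function(labels, cap = 2e5) {
  labels <- as.character(labels)
  tab <- table(labels)
  n <- length(labels)
  total <- exp(lgamma(n + 1) - sum(lgamma(tab + 1)))
  if (total > cap) {
    stop("exhaustive enumeration would require ", round(total),
         " arrangements (cap ", cap, ")")
  }
  lev <- names(tab)
  counts <- as.integer(tab)
  out <- vector("list", round(total))
  idx <- 0L
  cur <- character(n)
  recurse <- function(pos, counts) {
    if (pos > n) {
      idx <<- idx + 1L
      out[[idx]] <<- cur
      return(invisible())
    }
    for (k in seq_along(lev)) {
      if (counts[k] > 0L) {
        cur[pos] <<- lev[k]
        counts[k] <- counts[k] - 1L
        recurse(pos + 1L, counts)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  recurse(1L, counts)
  matrix(unlist(out), nrow = n)
}

# Tie-corrected Kruskal-Wallis over every column of a samples x taxa value
# matrix at once.  Ranks and tie corrections depend only on the data, so
# they are computed once and reused across label permutations; each
# permutation then costs a single rowsum().  This is what makes the
# 1,000-permutation cross-cohort overlap null affordable.
kw_rank_precompute <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  ranks <- apply(values, 2L, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = n)
  tie_corr <- apply(values, 2L, function(x) {
    t <- table(x)
    1 - sum(t^3 - t) / (n^3 - n)
  })
  list(ranks = ranks, tie_corr = tie_corr, n = n,
       labels = colnames(values))
}

kw_stat_from_ranks <- function(pre, groups) {
  groups <- as.factor(groups)
  n <- pre$n
  stopifnot(length(groups) == n)
  sizes <- as.vector(table(groups))
  rs <- rowsum(pre$ranks, groups)            # groups x taxa rank sums
  h0 <- 12 / (n * (n + 1)) * colSums(rs^2 / sizes) - 3 * (n + 1)
  h <- ifelse(pre$tie_corr > 0, h0 / pre$tie_corr, 0)
  h[h < 0 & h > -1e-9] <- 0                  # numerical guard
  p <- pchisq(h, df = nlevels(groups) - 1L, lower.tail = FALSE)
  p[pre$tie_corr <= 0] <- 1                  # constant column: no test
  list(H = h, p = p)
}

# Exact Kruskal-Wallis permutation tail for one value vector: enumerate all
# distinct group-label arrangements and count H* >= H_obs.
kw_exact_p <- function(x, groups, cap = 2e5) {
  pre <- kw_rank_precompute(matrix(x, ncol = 1))
  obs <- kw_stat_from_ranks(pre, groups)$H
  perms <- multiset_permutations(groups, cap = cap)
  hs <- apply(perms, 2L, function(g) kw_stat_from_ranks(pre, g)$H)
  mean(hs >= obs - 1e-12)
}

# Condensed (lower-triangle) vector of a square symmetric matrix.
condense <- function(m) m[lower.tri(m)]

# Pair index bookkeeping for a condensed vector over n samples.
pair_indices <- function(n) {
  j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
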