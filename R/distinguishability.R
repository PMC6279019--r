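#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of whether between-group distances exceed within-group
#' distances.  Condensed distances are ranked once (ties get average
#' ranks); `R = (mean between-group rank - mean within-group rank) /
#' (n(n-1)/4)`.  The permutation p-value uses the never-zero convention
#' `p = (1 + #[R* >= R]) / (1 + n_perm)`.  With `exhaustive = TRUE` every
#' distinct label assignment is enumerated instead and
#' `p = #[R* >= R] / #assignments` (the observed assignment is part of the
#' enumeration).
#'
#' @param dm a `distance_matrix`.
#' @param groups named group labels covering the matrix samples.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all distinct assignments (small n only).
#' @return Object of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `group_sizes`.
#' @export
anosim <- function(dm, groups, n_perm = 9999, seed = NULL,
                   exhaustive = FALSE) {
  stopifnot(inherits(dm, "distance_matrix"))
  groups <- groups[dm$sample_ids]
  if (anyNA(groups)) stop("groups must cover all samples in the matrix")
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) with a single member: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; remove or merge them before ANOSIM")
  n <- length(groups)
  r <- rank(condense(dm$values))
  idx <- pair_indices(n)
  r_stat <- function(g) {
    within <- g[idx[, "i"]] == g[idx[, "j"]]
    (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
  }
  obs <- r_stat(groups)
  if (exhaustive) {
    perms <- multiset_permutations(groups)
    stats <- apply(perms, 2L, r_stat)
    p <- mean(stats >= obs - 1e-12)
    np <- ncol(perms)
  } else {
    hits <- with_seed(seed, sum(vapply(seq_len(n_perm), function(i)
      r_stat(sample(groups)) >= obs - 1e-12, logical(1))))
    p <- (1 + hits) / (1 + n_perm)
    np <- n_perm
  }
  structure(list(R = obs, p = p, n_permutations = np,
                 group_sizes = as.list(sizes)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM R = ", fmt_num(x$R), ", p = ", fmt_num(x$p),
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' ANOSIM with repeated subsampling of over-represented groups
#'
#' Groups larger than `subset_size` are down-sampled without replacement to
#' `subset_size` in each repetition; R and p are averaged across the
#' repetitions.  This counteracts the dominance of a heavily sampled
#' majority group.
#'
#' @inheritParams anosim
#' @param subset_size per-group cap (>= 2).
#' @param n_reps subsampling repetitions.
#' @return `anosim_result` with averaged `R` and `p`, plus `per_rep`.
#' @export
anosim_subsampled <- function(dm, groups, subset_size, n_reps = 10,
                              n_perm = 9999, seed = NULL) {
  stopifnot(subset_size >= 2)
  groups <- groups[dm$sample_ids]
  sizes <- table(as.character(groups))
  if (all(sizes < subset_size))
    stop("every group is below subset_size ", subset_size)
  seeds <- derive_seeds(seed, 2L * n_reps)
  reps <- lapply(seq_len(n_reps), function(rep) {
    keep <- unlist(lapply(names(sizes), function(g) {
      ids <- dm$sample_ids[groups == g]
      if (length(ids) > subset_size)
        with_seed(seeds[[rep]], sample(ids, subset_size))
      else ids
    }))
    anosim(subset_distance_matrix(dm, keep), groups[keep], n_perm = n_perm,
           seed = seeds[[n_reps + rep]])
  })
  structure(list(R = mean(vapply(reps, `[[`, numeric(1), "R")),
                 p = mean(vapply(reps, `[[`, numeric(1), "p")),
                 n_permutations = n_perm, group_sizes = as.list(sizes),
                 per_rep = reps, subset_size = subset_size),
            class = "anosim_result")
}

#' ANOSIM group-ablation ledger
#'
#' Runs ANOSIM for every configuration in the ablation design: all groups,
#' each single group removed, and each pair of groups alone.  For G groups
#' this yields `1 + G + choose(G, 2)` entries (11 at G = 4).  Retained sets
#' with fewer than two groups are skipped with a note.
#'
#' @inheritParams anosim
#' @return data.frame ledger: `retained` (group set key), `n_groups`, `R`,
#'   `p`, `n_perm`, `note`.
#' @export
anosim_ablation <- function(dm, groups, n_perm = 9999, seed = NULL) {
  groups <- groups[dm$sample_ids]
  glev <- sort(unique(as.character(groups)))
  if (length(glev) < 3) stop("ablation needs at least 3 groups")
  configs <- c(list(glev),
               lapply(glev, function(g) setdiff(glev, g)),
               combn(glev, 2, simplify = FALSE))
  seeds <- derive_seeds(seed, length(configs))
  rows <- lapply(seq_along(configs), function(k) {
    retained <- configs[[k]]
    key <- paste(retained, collapse = "+")
    if (length(retained) < 2)
      return(data.frame(retained = key, n_groups = length(retained),
                        R = NA, p = NA, n_perm = NA,
                        note = "skipped: fewer than 2 groups"))
    keep <- dm$sample_ids[groups %in% retained]
    res <- anosim(subset_distance_matrix(dm, keep), groups[keep],
                  n_perm = n_perm, seed = seeds[[k]])
    data.frame(retained = key, n_groups = length(retained), R = res$R,
               p = res$p, n_perm = n_perm, note = "")
  })
  do.call(rbind, rows)
}

#' PERMANOVA on a distance matrix (optionally averaged over rarefactions)
#'
#' Sequential (Type-I) sums of squares in the listed term order, fitted
#' with \code{vegan::adonis2}; pseudo-F per term, permutation of raw data
#' rows.  When a list of rarefied matrices is supplied the per-term
#' statistics are averaged across them.  Constant or single-level terms
#' are flagged and dropped (zero df).
#'
#' @param dm a `distance_matrix` or a list of them (e.g. one per
#'   rarefaction).
#' @param metadata data.frame with `sample_id` and the term columns.
#' @param terms model terms, fitted in this order.
#' @param n_perm permutations per matrix.
#' @param seed RNG seed.
#' @return Object of class `permanova_result`: `table` (term, df, SS,
#'   pseudo-F, R2, p; includes Residual and Total rows), `n_matrices`,
#'   `dropped_terms`.
#' @export
permanova <- function(dm, metadata, terms = c("ethnicity", "age", "sex", "bmi"),
                      n_perm = 999, seed = NULL) {
  dms <- if (inherits(dm, "distance_matrix")) list(dm) else dm
  stopifnot(all(vapply(dms, inherits, logical(1), "distance_matrix")))
  missing_terms <- setdiff(terms, names(metadata))
  if (length(missing_terms) > 0)
    stop("terms absent from metadata: ", paste(missing_terms, collapse = ", "))
  md <- metadata[match(dms[[1]]$sample_ids, metadata$sample_id), , drop = FALSE]
  dropped <- terms[vapply(terms, function(tm)
    length(unique(na.omit(md[[tm]]))) < 2, logical(1))]
  if (length(dropped) > 0) {
    warning("constant term(s) dropped (zero df): ",
            paste(dropped, collapse = ", "))
    terms <- setdiff(terms, dropped)
  }
  if (length(terms) == 0) stop("no usable terms")
  seeds <- derive_seeds(seed, length(dms))
  tabs <- lapply(seq_along(dms), function(k) {
    md_k <- metadata[match(dms[[k]]$sample_ids, metadata$sample_id), ,
                     drop = FALSE]
    d <- as.dist(dms[[k]]$values)
    fml <- as.formula(paste("d ~", paste(terms, collapse = " + ")),
                      env = environment())
    with_seed(seeds[[k]], {
      a <- vegan::adonis2(fml, data = md_k, permutations = n_perm,
                          by = "terms")
      data.frame(term = rownames(a), df = a$Df, SS = a$SumOfSqs,
                 pseudo_F = a$F, R2 = a$R2, p = a$`Pr(>F)`,
                 stringsAsFactors = FALSE)
    })
  })
  avg <- tabs[[1]]
  if (length(tabs) > 1) {
    for (colm in c("SS", "pseudo_F", "R2", "p")) {
      avg[[colm]] <- rowMeans(do.call(cbind, lapply(tabs, `[[`, colm)))
    }
  }
  structure(list(table = avg, n_matrices = length(dms),
                 dropped_terms = dropped, n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (sequential SS",
      if (x$n_matrices > 1) paste0(", averaged over ", x$n_matrices, " matrices"),
      ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Encode metadata variables as a numeric block: continuous centred/scaled,
# categorical full-rank dummy coded (reference level dropped).
encode_metadata_block <- function(md, variables) {
  cols <- lapply(variables, function(v) {
    x <- md[[v]]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2) matrix(0, length(x), 1,
                                        dimnames = list(NULL, v))
      else matrix(as.vector(scale(x)), ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      if (nlevels(f) < 2) matrix(0, length(x), 1, dimnames = list(NULL, v))
      else model.matrix(~f)[, -1, drop = FALSE]
    }
  })
  do.call(cbind, cols)
}

#' Adapted BioEnv (BEST) permutation test
#'
#' Correlates a community distance matrix with the Euclidean distance
#' matrix over an encoded metadata block (continuous variables centred and
#' scaled, categorical variables full-rank dummy coded), by Spearman
#' correlation of the two condensed distance vectors.  Significance for
#' each variable of interest is obtained by shuffling only that variable's
#' values between samples `n_shuffles` times and counting how often the
#' shuffled correlation reaches the observed one:
#' `p = (1 + #[rho* >= rho]) / (1 + n_shuffles)`.
#'
#' @param dm a `distance_matrix`.
#' @param metadata data.frame with `sample_id` and the variables.
#' @param variables variables entering the metadata block.
#' @param targets variables to compute a shuffle p-value for (default all).
#' @param n_shuffles shuffles per target.
#' @param seed RNG seed.
#' @return Object of class `bioenv_result`: `rho`, `p` (named by target),
#'   `n_shuffles`.
#' @export
bioenv_adapted <- function(dm, metadata, variables = c("ethnicity", "age",
                                                       "sex", "bmi"),
                           targets = variables, n_shuffles = 1000,
                           seed = NULL) {
  stopifnot(all(targets %in% variables))
  md <- metadata[match(dm$sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(match(dm$sample_ids, metadata$sample_id)))
    stop("metadata does not cover all samples")
  comm <- condense(dm$values)
  block_dist <- function(md) condense(as.matrix(dist(
    encode_metadata_block(md, variables))))
  obs_rho <- cor(comm, block_dist(md), method = "spearman")
  seeds <- derive_seeds(seed, length(targets))
  p <- setNames(numeric(length(targets)), targets)
  for (k in seq_along(targets)) {
    tg <- targets[k]
    if (length(unique(md[[tg]])) < 2) {
      warning("target '", tg, "' is constant; p = 1")
      p[k] <- 1
      next
    }
    hits <- with_seed(seeds[[k]], {
      sum(vapply(seq_len(n_shuffles), function(i) {
        md2 <- md
        md2[[tg]] <- sample(md2[[tg]])
        cor(comm, block_dist(md2), method = "spearman") >= obs_rho - 1e-12
      }, logical(1)))
    })
    p[k] <- (1 + hits) / (1 + n_shuffles)
  }
  structure(list(rho = obs_rho, p = p, n_shuffles = n_shuffles),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat("Adapted BioEnv: Spearman rho = ", fmt_num(x$rho), "\n", sep = "")
  for (v in names(x$p))
    cat("  p(", v, ") = ", fmt_num(x$p[[v]]), "\n", sep = "")
  invisible(x)
}
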