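test_that("distance partitions count pairs correctly in both modes", {
  m <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  dm <- distance_matrix(m)
  g <- setNames(c("A", "A", "B", "B"), letters[1:4])
  ap <- partition_distances(dm, g, "all_pairs")
  expect_equal(lengths(ap$intra), c(A = 1, B = 1))
  expect_equal(lengths(ap$inter), c("A|B" = 4))
  # conservation: multiset sizes sum to n(n-1)/2
  expect_equal(sum(lengths(ap$intra)) + sum(lengths(ap$inter)), 6)
  pm <- partition_distances(dm, g, "per_individual_mean")
  # one point per individual for its own group, one per (individual,
  # comparison group) across groups
  expect_equal(sum(lengths(pm$intra)), 4)
  expect_equal(sum(lengths(pm$inter)), 4)
  # all distances equal c: every partition statistic equals c
  expect_true(all(unlist(ap$intra) == 0.5) && all(unlist(ap$inter) == 0.5))
  expect_true(all(unlist(pm$intra) == 0.5) && all(unlist(pm$inter) == 0.5))
  # size-1 group flagged with empty intra multiset
  g2 <- setNames(c("A", "A", "A", "B"), letters[1:4])
  expect_equal(partition_distances(dm, g2, "per_individual_mean")$flagged, "B")
})

test_that("distance-set tests match closed forms and combinatorics", {
  # identical intra multisets: MWU p = 1 (two-sided, no continuity correction)
  part <- structure(list(
    intra = list(A = c(0.1, 0.2, 0.3), B = c(0.1, 0.2, 0.3)),
    inter = list("A|B" = c(0.1, 0.2, 0.3)),
    mode = "all_pairs", flagged = character(0)),
    class = "distance_partition")
  res <- compare_distance_sets(part)
  ii <- res$contrasts[res$contrasts$type == "intra_intra", ]
  expect_equal(ii$p, 1)
  # complete separation at n = 50: far below 1e-15 (exact bound 2/C(100,50))
  set.seed(1)
  part2 <- structure(list(
    intra = list(A = runif(50, 0, 0.5), B = runif(50, 0, 0.5)),
    inter = list("A|B" = runif(50, 0.5, 1)),
    mode = "all_pairs", flagged = character(0)),
    class = "distance_partition")
  res2 <- compare_distance_sets(part2)
  iv <- res2$contrasts[res2$contrasts$type == "intra_inter", ]
  expect_true(all(iv$p < 1e-15))
  # 4 groups: 6 intra-intra and 4 intra-inter contrasts
  set.seed(2)
  part3 <- structure(list(
    intra = setNames(lapply(1:4, function(i) runif(10)), LETTERS[1:4]),
    inter = setNames(lapply(1:6, function(i) runif(10)),
                     apply(combn(LETTERS[1:4], 2), 2, paste, collapse = "|")),
    mode = "all_pairs", flagged = character(0)),
    class = "distance_partition")
  res3 <- compare_distance_sets(part3)
  expect_equal(sum(res3$contrasts$type == "intra_intra"), 6)
  expect_equal(sum(res3$contrasts$type == "intra_inter"), 4)
  expect_equal(res3$contrasts$p_bonf[res3$contrasts$type == "intra_intra"],
               pmin(1, res3$contrasts$p[res3$contrasts$type == "intra_intra"] * 6))
})

test_that("intra-group distances are lower than inter-group under a planted effect", {
  cfg <- simulation_config(seed = 101, n_samples_per_group = c(A = 30, B = 30),
                           n_otus = 80, depth_range = c(3000, 3000),
                           planted_taxa = list(
                             planted_effect("f__F01", "B", fold_change = 10),
                             planted_effect("f__F02", "A", fold_change = 10)))
  co <- generate_cohort(cfg)
  g <- setNames(co$metadata$ethnicity, co$metadata$sample_id)
  dm <- beta_diversity(co$table, "bray_curtis")
  part <- partition_distances(dm, g, "all_pairs")
  expect_lt(mean(unlist(part$intra)), mean(unlist(part$inter)))
})

test_that("ubiquity uses inclusive >= semantics and the A/U arithmetic is exact", {
  # o1 present in exactly 5/10 samples -> included at threshold 0.5
  counts <- matrix(0L, 10, 3,
                   dimnames = list(sprintf("s%02d", 1:10), c("o1", "o2", "o3")))
  counts[1:5, "o1"] <- 20L
  counts[1:4, "o2"] <- 10L
  counts[, "o3"] <- 80L
  tb <- count_table(counts)
  g <- setNames(rep("G", 10), rownames(counts))
  ub <- ubiquitous_otus(tb, g, threshold = 0.5)
  expect_true("o1" %in% ub$groups$G$ubiquitous)
  expect_false("o2" %in% ub$groups$G$ubiquitous)
  st <- ub$groups$G$stats
  expect_equal(st$au[st$otu == "o1"],
               st$mean_abundance[st$otu == "o1"] / 0.5)
  # mean abundance 0.02 at ubiquity 0.8 -> A/U = 0.025
  expect_equal(0.02 / 0.8, 0.025)
})

test_that("the abundance-ubiquity regression is exact on a linear construction", {
  # products k*c = 315 * 2^k for k in {6..10}: log10(mean abundance) is an
  # exact linear function of ubiquity with slope 10*log10(2)
  ks <- 6:10
  cs <- as.integer(315 * 2^ks / ks)
  n <- 10; D <- 70000L
  counts <- matrix(0L, n, 7,
                   dimnames = list(sprintf("s%02d", 1:n),
                                   c(paste0("o", ks), "fill1", "fill2")))
  for (j in seq_along(ks)) counts[seq_len(ks[j]), j] <- cs[j]
  load <- rowSums(counts)
  counts[1:5, "fill1"] <- D - load[1:5]
  counts[6:10, "fill2"] <- D - load[6:10]
  tb <- count_table(counts)
  g <- setNames(rep("G", n), rownames(counts))
  ub <- ubiquitous_otus(tb, g, threshold = 0.55)
  reg <- ub$groups$G$regression
  expect_equal(reg$r2, 1, tolerance = 1e-9)
  expect_equal(reg$slope, 10 * log10(2), tolerance = 1e-9)
  # fillers (ubiquity 0.5) are below the qualifying threshold
  expect_setequal(ub$groups$G$ubiquitous, paste0("o", ks))
})

test_that("doubling pre-closure abundances leaves ubiquity unchanged", {
  cfg <- simulation_config(seed = 111, n_samples_per_group = c(A = 10),
                           n_otus = 30, depth_range = c(2000, 2000))
  tb <- generate_cohort(cfg)$table
  g <- setNames(rep("A", 10), tb$sample_ids)
  u1 <- ubiquitous_otus(tb, g)$groups$A$stats$ubiquity
  tb2 <- count_table(tb$counts * 2L, tb$taxonomy)
  u2 <- ubiquitous_otus(tb2, g)$groups$A$stats$ubiquity
  expect_equal(u1, u2)
})

test_that("co-occurrence clustering recovers a planted block and its associates", {
  set.seed(21)
  n <- 200
  z <- rnorm(n)
  e <- matrix(rnorm(n * 6, sd = 0.7), n, 6)
  block <- z + e                                  # 6 mutually correlated families
  assoc <- e[, 1] + e[, 2] + e[, 3]               # linked to exactly 3 members
  indep <- matrix(rnorm(n * 8), n, 8)             # unlinked families
  raw <- cbind(block, assoc, indep)
  colnames(raw) <- paste0("f", 1:15)
  vals <- exp(0.15 * raw)
  vals <- cbind(vals, remainder = 60)             # near-constant closure
  tt <- taxon_table(vals, "family")
  ext <- setNames(c(rep(1e-4, 6), rep(0.5, 10)), colnames(vals))
  cc <- cooccurrence_clusters(tt, external_assoc_p = ext)
  main <- cc$clusters[[which.max(lengths(cc$clusters))]]
  expect_true(all(paste0("f", 1:6) %in% main))
  expect_false("f7" %in% main)
  expect_true("f7" %in% cc$cluster_associated[[which.max(lengths(cc$clusters))]])
  # enrichment: members' external p-values lower than non-members'
  expect_lt(cc$enrichment$p, 0.05)
  # an independent family has all its edges to the block masked
  expect_true(all(!cc$mask["f9", paste0("f", 1:6)]))
})

test_that("proportional families are perfectly correlated and constant ones excluded", {
  set.seed(22)
  base <- runif(50, 1, 5)
  vals <- cbind(fa = base, fb = 3 * base, fc = runif(50), fd = runif(50),
                const = 1)
  vals <- cbind(vals, fill = 30 - rowSums(vals))  # constant row sums: closure
  tt <- taxon_table(vals, "family")               # keeps `const` constant
  expect_warning(cc <- cooccurrence_clusters(tt), "constant")
  expect_equal(cc$rho["fa", "fb"], 1)
  expect_true(cc$mask["fa", "fb"])
  expect_false("const" %in% colnames(cc$rho))
})
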