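test_that("Kruskal-Wallis screening matches stats::kruskal.test and the exact oracle", {
  set.seed(31)
  vals <- matrix(runif(12 * 8), 12, 8,
                 dimnames = list(sprintf("s%02d", 1:12), paste0("t", 1:8)))
  vals[, 3] <- rep(1:3, each = 4) + runif(12, 0, 0.2)   # some ties via rounding
  vals[, 4] <- round(vals[, 4], 1)
  tt <- taxon_table(cbind(vals, rest = 10), "genus")
  g <- setNames(rep(c("A", "B", "C"), each = 4), rownames(vals))
  rec <- kruskal_by_group(tt, g)
  for (tx in paste0("t", 1:8)) {
    ref <- kruskal.test(tt$values[, tx], factor(g))
    expect_equal(rec$H[rec$taxon == tx], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(rec$p[rec$taxon == tx], ref$p.value, tolerance = 1e-12)
  }
  expect_false(is.unsorted(rec$p))

  # exact enumeration: 2 groups of 3, complete separation -> tail of 20
  x <- c(1, 2, 3, 10, 11, 12)
  tt2 <- taxon_table(matrix(c(x, rep(5, 6)), 6, 2,
                            dimnames = list(sprintf("e%d", 1:6), c("tx", "rest"))),
                     "genus")
  g2 <- setNames(rep(c("A", "B"), each = 3), sprintf("e%d", 1:6))
  rec2 <- kruskal_by_group(tt2, g2, exact = TRUE)
  oracle_p <- oracle_exact_tail(tt2$values[, "tx"], unname(g2), oracle_kw_H)
  expect_equal(rec2$p[rec2$taxon == "tx"], oracle_p)
  expect_equal(rec2$p[rec2$taxon == "tx"], 2 / 20)
})

test_that("constant and all-zero taxa are flagged with H = 0, p = 1", {
  varies <- runif(8)
  vals <- cbind(flat = rep(0.2, 8), zero = 0, varies = varies,
                rest = 3 - varies)              # constant row sums: closure
  rownames(vals) <- sprintf("s%d", 1:8)         # keeps `flat` constant
  tt <- taxon_table(vals, "genus")
  g <- setNames(rep(c("A", "B"), each = 4), rownames(vals))
  rec <- kruskal_by_group(tt, g)
  expect_equal(rec$H[rec$taxon == "flat"], 0)
  expect_equal(rec$p[rec$taxon == "flat"], 1)
  expect_true(rec$flagged[rec$taxon == "zero"])
  expect_equal(rec$p[rec$taxon == "zero"], 1)
})

test_that("BH adjustment is invariant to taxon order", {
  set.seed(32)
  vals <- matrix(runif(20 * 15), 20, 15,
                 dimnames = list(sprintf("s%02d", 1:20), paste0("t", 1:15)))
  g <- setNames(rep(c("A", "B"), each = 10), rownames(vals))
  r1 <- kruskal_by_group(taxon_table(vals, "genus"), g)
  perm <- sample(ncol(vals))
  r2 <- kruskal_by_group(taxon_table(vals[, perm], "genus"), g)
  m <- match(r1$taxon, r2$taxon)
  expect_equal(r1$p_fdr, r2$p_fdr[m], tolerance = 1e-12)
  expect_equal(r1$p_bonf, r2$p_bonf[m], tolerance = 1e-12)
  expect_true(all(r1$p <= r1$p_bonf + 1e-15))
})

test_that("replication overlap counts identically-labelled significant taxa", {
  mk <- function(taxa, sig_taxa) {
    data.frame(taxon = taxa, p = 0.5, p_fdr = ifelse(taxa %in% sig_taxa, 0.01, 0.5))
  }
  universe <- paste0("tax", 1:500)
  sigA <- universe[1:130]
  sigB <- universe[c(1:25, 201:220)]          # 45 significant, 25 shared
  ra <- mk(universe, sigA); rb <- mk(universe, sigB)
  res <- replication_overlap(list(genus = ra), list(genus = rb))
  expect_equal(res$overlap_total, 25)
  expect_equal(res$per_rank$n_sig_a, 130)
  expect_equal(res$per_rank$n_sig_b, 45)
  # self-comparison: overlap equals the significant set
  self <- replication_overlap(list(genus = ra), list(genus = ra))
  expect_equal(self$overlap_total, 130)
  # disjoint sets
  disj <- replication_overlap(list(genus = mk(universe, universe[1:10])),
                              list(genus = mk(universe, universe[11:20])))
  expect_equal(disj$overlap_total, 0)
  # enrichment over the 5% chance expectation is detected
  expect_lt(res$fisher$B$p, 0.05)
})

test_that("the overlap permutation null is exceeded by planted shared effects", {
  shared <- lapply(sprintf("OTU_%04d", 1:4), function(id)
    planted_effect(id, "B", fold_change = 8))
  pair <- generate_paired_cohorts(
    simulation_config(seed = 121, n_samples_per_group = c(A = 40, B = 40),
                      n_otus = 60, depth_range = c(5000, 5000), id_prefix = "A"),
    simulation_config(seed = 122, n_samples_per_group = c(A = 40, B = 40),
                      n_otus = 60, depth_range = c(5000, 5000), id_prefix = "B"),
    shared)
  gA <- setNames(pair$A$metadata$ethnicity, pair$A$metadata$sample_id)
  gB <- setNames(pair$B$metadata$ethnicity, pair$B$metadata$sample_id)
  ttA <- collapse_taxonomy(pair$A$table, "genus")
  ttB <- collapse_taxonomy(pair$B$table, "genus")
  res <- overlap_permutation_null(ttA, gA, ttB, gB, n_perm = 99, seed = 9)
  expect_gt(res$observed_overlap[["combined"]], 0)
  expect_equal(unname(res$perm_p[["combined"]]), 1 / 100)
  expect_error(overlap_permutation_null(ttA, gA, ttB, gB, n_perm = 0), ">= 1")
})

test_that("redundant family/genus pairs collapse by the 82% rule", {
  ids <- sprintf("s%02d", 1:10)
  g <- setNames(rep(c("A", "B"), each = 5), ids)
  fam_lab <- function(f) sprintf("k__Bacteria; p__P1; c__C1; o__O1; f__%s", f)
  gen_lab <- function(f, gn) paste0(fam_lab(f), "; g__", gn)
  # f1: single classified genus at 100%; f2: unclassified genus at 95%;
  # f3: two genera at 60/40
  gcounts <- cbind(100, 95, 5, 60, 40)
  gen_counts <- matrix(as.integer(gcounts[rep(1, 10), ]), 10, 5,
                       dimnames = list(ids, c(gen_lab("F1", "G1"),
                                              gen_lab("F2", "Unclassified"),
                                              gen_lab("F2", "G2"),
                                              gen_lab("F3", "G3"),
                                              gen_lab("F3", "G4"))))
  fam_counts <- matrix(as.integer(cbind(100, 100, 100)[rep(1, 10), ]), 10, 3,
                       dimnames = list(ids, c(fam_lab("F1"), fam_lab("F2"),
                                              fam_lab("F3"))))
  fam_tt <- taxon_table(fam_counts, "family")
  gen_tt <- taxon_table(gen_counts, "genus")
  taxa <- c(colnames(fam_counts), gen_lab("F1", "G1"),
            gen_lab("F2", "Unclassified"), gen_lab("F3", "G3"))
  out <- collapse_redundant_taxa(taxa, fam_tt, gen_tt, g)
  expect_false(out$kept[out$taxon == fam_lab("F1")])       # genus representative
  expect_true(out$kept[out$taxon == gen_lab("F1", "G1")])
  expect_true(out$kept[out$taxon == fam_lab("F2")])        # unclassified genus
  expect_false(out$kept[out$taxon == gen_lab("F2", "Unclassified")])
  expect_true(out$kept[out$taxon == fam_lab("F3")])        # 60% < 82%
  expect_true(out$kept[out$taxon == gen_lab("F3", "G3")])
})

test_that("pairwise shifts enumerate C(4,2) tests and replicate planted directions", {
  set.seed(33)
  mk_cohort <- function(seed) {
    n <- 30
    ids <- sprintf("c%d_%02d", seed, 1:(4 * n))
    g <- setNames(rep(LETTERS[1:4], each = n), ids)
    x <- c(rnorm(n, 5), rnorm(n, 1), rnorm(n, 5), rnorm(n, 5))  # B reduced
    vals <- cbind(tx = pmax(x, 0), rest = 10)
    rownames(vals) <- ids
    list(tt = taxon_table(vals, "genus"), g = g)
  }
  a <- mk_cohort(1); b <- mk_cohort(2)
  sa <- pairwise_group_shifts(a$tt, a$g)
  sb <- pairwise_group_shifts(b$tt, b$g)
  expect_equal(sum(sa$taxon == "tx"), 6)
  expect_equal(sa$p_bonf, pmin(1, sa$p * 6))
  rep_out <- replicate_shifts(sa, sb)
  b_rows <- rep_out[rep_out$taxon == "tx" &
                      (rep_out$group_a == "B" | rep_out$group_b == "B"), ]
  expect_equal(nrow(b_rows), 3)
  expect_true(all(b_rows$replicated))
  # direction: B lower than every other group on both sides of the pair order
  expect_true(all(ifelse(b_rows$group_b == "B",
                         b_rows$direction_abundance_a == "down",
                         b_rows$direction_abundance_a == "up")))
  non_b <- rep_out[rep_out$taxon == "tx" & rep_out$group_a != "B" &
                     rep_out$group_b != "B", ]
  expect_true(all(!non_b$replicated))
})

test_that("covariate regressions recover an exact linear construction", {
  set.seed(34)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  md <- data.frame(sample_id = ids,
                   ethnicity = rep(c("Caucasian", "Hispanic"), each = n / 2),
                   sex = rep(c("male", "female"), n / 2),
                   age = runif(n, 18, 55), bmi = runif(n, 18, 35))
  p <- 10^(-3 + 0.05 * md$bmi)                  # exact log-linear in BMI
  vals <- cbind(tx = p, rest = 1 - p)
  rownames(vals) <- ids
  tt <- taxon_table(vals, "family")
  res <- abundance_regressions(tt, md)
  row <- res[res$taxon == "tx", ]
  expect_false(row$lin_skipped)
  expect_equal(row$lin_r2, 1, tolerance = 1e-9)
  expect_lt(row$term_p_bmi, 1e-12)
  # taxon present everywhere: logistic fit is degenerate and skipped
  expect_true(row$log_skipped)
  # taxon absent everywhere: both fits skipped
  vals2 <- cbind(gone = rep(0, n), rest = 1)
  rownames(vals2) <- ids
  res2 <- abundance_regressions(taxon_table(vals2, "family"), md)
  expect_true(res2$lin_skipped[res2$taxon == "gone"])
  expect_true(res2$log_skipped[res2$taxon == "gone"])
})

test_that("logistic presence p-values are uniform when presence is group-independent", {
  set.seed(35)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  md <- data.frame(sample_id = ids,
                   ethnicity = rep(c("Caucasian", "Hispanic"), each = n / 2),
                   sex = sample(c("male", "female"), n, TRUE),
                   age = runif(n, 18, 55), bmi = runif(n, 18, 35))
  ps <- replicate(80, {
    pres <- rbinom(n, 1, 0.5)
    vals <- cbind(tx = pres * runif(n, 0.1, 0.3), rest = 1)
    rownames(vals) <- ids
    suppressWarnings(
      abundance_regressions(taxon_table(vals, "family"), md,
                            min_possessors = 1000)$log_p[1])
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("presence-phenotype tests detect a downward shift and handle degenerate input", {
  set.seed(36)
  ids <- sprintf("s%03d", 1:200)
  pres <- setNames(rep(c(TRUE, FALSE), 100), ids)
  pheno <- setNames(rnorm(200, mean = ifelse(pres, 23, 25)), ids)
  g <- setNames(rep(c("X", "X", "Y", "Y"), 50), ids)
  res <- presence_phenotype_test(pres, pheno, g)
  expect_lt(res$p[res$scope == "overall"], 0.001)
  expect_equal(nrow(res), 3)
  # identical distributions: one-tailed p averages ~0.5
  ps <- replicate(100, {
    ph <- setNames(rnorm(40), names(pres)[1:40])
    presence_phenotype_test(pres[1:40], ph)$p[1]
  })
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
  # everyone possesses the taxon: skipped with diagnostic
  all_pres <- setNames(rep(TRUE, 10), ids[1:10])
  res2 <- presence_phenotype_test(all_pres, pheno[1:10])
  expect_true(res2$skipped[1])
})

test_that("RF feature preparation applies the rarest-group presence filter", {
  cfg <- simulation_config(seed = 141,
                           n_samples_per_group = c(A = 13, B = 40),
                           n_otus = 40, depth_range = c(10000, 12000))
  co <- generate_cohort(cfg)
  g <- setNames(co$metadata$ethnicity, co$metadata$sample_id)
  fe <- prepare_rf_features(co$table, g, depth = 10000, seed = 1)
  expect_equal(fe$presence_threshold, 6)     # floor(13/2)
  cfg2 <- simulation_config(seed = 142,
                            n_samples_per_group = c(A = 10, B = 40),
                            n_otus = 40, depth_range = c(10000, 12000))
  co2 <- generate_cohort(cfg2)
  g2 <- setNames(co2$metadata$ethnicity, co2$metadata$sample_id)
  fe2 <- prepare_rf_features(co2$table, g2, depth = 10000, seed = 1)
  expect_equal(fe2$presence_threshold, 5)    # floor(10/2)
  # arcsin-sqrt transform keeps features in [0, pi/2]
  expect_true(all(fe$features >= 0 & fe$features <= pi / 2 + 1e-9))
})

test_that("a separable feature yields AUC 1 and resampling balances classes", {
  set.seed(37)
  n <- 90
  ids <- sprintf("s%03d", 1:n)
  g <- setNames(c(rep("target_grp", 20), rep("other", 70)), ids)
  x <- cbind(sep = c(runif(20, 0.8, 1), runif(70, 0, 0.2)),
             noise = runif(n))
  rownames(x) <- ids
  rep_smote <- rf_one_vs_all(x, g, sampling = "smote", k = 5, seed = 1,
                             ntree = 100)
  expect_equal(rep_smote$target_grp$auc, 1)
  expect_equal(names(which.max(rep_smote$target_grp$importance)), "sep")
  expect_equal(max(rep_smote$target_grp$importance), 100)

  y <- factor(ifelse(g == "target_grp", "target", "rest"))
  ds <- down_sample(x, y)
  expect_equal(unname(table(ds$y)["target"]), unname(table(ds$y)["rest"]))
  sm <- smote_sample(x, y)
  expect_equal(unname(table(sm$y)["target"]), 40)   # min(70, 2*20)
  expect_equal(unname(table(sm$y)["rest"]), 40)
  # synthetic points interpolate within the minority convex hull
  synth <- sm$x[grepl("synth", rownames(sm$x)), "sep"]
  expect_true(all(synth >= 0.8 & synth <= 1))
})
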