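test_that("classic OTU table round-trips bit-exactly", {
  tb <- tiny_count_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classic_otu_table(tb, path)
  back <- read_count_table(path, "classic_tsv")
  expect_identical(back$counts, tb$counts)
  expect_identical(back$taxonomy, tb$taxonomy)
  # leading "Constructed from biom file" comment is tolerated
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_classic_otu_table(tb, path2, biom_header = TRUE)
  expect_identical(readLines(path2)[1], "# Constructed from biom file")
  expect_identical(read_count_table(path2)$counts, tb$counts)
})

test_that("count validation names the offending cell", {
  m <- matrix(c(1L, -1L, 2L, 3L), 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  expect_error(count_table(m), "s2.*o1|o1.*s2")
  m2 <- matrix(c(1, 2.5, 2, 3), 2,
               dimnames = list(c("s1", "s2"), c("o1", "o2")))
  expect_error(count_table(m2), "integer")
  dup <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("o1", "o2")))
  expect_error(count_table(dup), "duplicate sample")
})

test_that("BIOM-JSON tables are read through biomformat", {
  tb <- tiny_count_table()
  b <- biomformat::make_biom(t(tb$counts))
  path <- withr::local_tempfile(fileext = ".biom")
  suppressWarnings(biomformat::write_biom(b, path))
  back <- suppressWarnings(read_count_table(path, "biom_json"))
  expect_equal(unname(back$counts[tb$sample_ids, tb$otu_ids]),
               unname(tb$counts))
})

test_that("metadata TSV round-trips with a #SampleID header", {
  md <- qc_metadata(c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, path)
  expect_true(startsWith(readLines(path)[1], "#SampleID"))
  back <- read_metadata(path)
  expect_equal(back, md)
})

test_that("QC removes samples in the documented order and reports attrition", {
  n <- 10
  ids <- sprintf("s%02d", 1:n)
  counts <- matrix(0L, n, 5, dimnames = list(ids, paste0("o", 1:5)))
  counts[, 1:3] <- 400L                       # healthy samples: depth 1200
  counts["s09", ] <- c(999L, 0L, 0L, 1L, 0L)  # 1000 reads, 999 after OTU filter
  tb <- count_table(counts)
  md <- qc_metadata(ids)
  md$bmi[1] <- 65        # bmi_high
  md$bmi[2] <- 8         # bmi_low
  md$age[3] <- NA        # age_missing
  md$age[4] <- 60        # age_high
  md$age[5] <- 17        # age_low
  md$ethnicity[6] <- "other"
  md$body_site[7] <- "oral"
  md$sex[8] <- "other"
  res <- apply_qc(tb, md, qc_config())
  rep <- res$report
  expect_equal(rep$removed[rep$step == "bmi_high"], 1)
  expect_equal(rep$removed[rep$step == "bmi_low"], 1)
  expect_equal(rep$removed[rep$step == "age_missing"], 1)
  expect_equal(rep$removed[rep$step == "age_high"], 1)
  expect_equal(rep$removed[rep$step == "age_low"], 1)
  expect_equal(rep$removed[rep$step == "ethnicity_unknown"], 1)
  expect_equal(rep$removed[rep$step == "not_fecal"], 1)
  expect_equal(rep$removed[rep$step == "sex_unknown"], 1)
  expect_equal(rep$removed[rep$step == "otu_min_total"], 2)
  expect_equal(rep$removed[rep$step == "sample_min_depth"], 1)
  expect_setequal(res$table$sample_ids, c("s10"))
  # a sample failing several filters is charged to the first failing step
  md2 <- qc_metadata(ids[1:2])
  md2$bmi[1] <- 70; md2$age[1] <- 17
  counts2 <- matrix(1000L, 2, 2, dimnames = list(ids[1:2], c("o1", "o2")))
  res2 <- apply_qc(count_table(counts2), md2)
  expect_equal(res2$report$removed[res2$report$step == "bmi_high"], 1)
  expect_equal(res2$report$removed[res2$report$step == "age_low"], 0)
})

test_that("QC is idempotent and errors when nothing survives", {
  cfg <- simulation_config(seed = 71, n_samples_per_group = c(A = 10, B = 10),
                           n_otus = 40, depth_range = c(1500, 3000))
  co <- generate_cohort(cfg)
  md <- co$metadata
  md$ethnicity <- ifelse(md$ethnicity == "A", "Caucasian", "Hispanic")
  once <- apply_qc(co$table, md)
  twice <- apply_qc(once$table, once$metadata)
  expect_identical(once$table$counts, twice$table$counts)
  expect_equal(sum(twice$report$removed), 0)

  bad_md <- md
  bad_md$body_site <- "oral"
  expect_error(apply_qc(co$table, bad_md), "all samples removed")
})

test_that("taxonomy collapse sums counts, closes rows, and keeps unclassified ranks distinct", {
  tb <- tiny_count_table()
  fam <- collapse_taxonomy(tb, "family")
  # o1+o2+o3 share f__FX: sample s1 has 5+0+3 = 8 of depth 20
  fx <- grep("f__FX", fam$taxa, value = TRUE)
  expect_equal(unname(fam$values["s1", fx]), 8 / 20)
  # mass conservation pre-closure
  expect_equal(rowSums(fam$counts), rowSums(tb$counts))

  gen <- collapse_taxonomy(tb, "genus")
  expect_true(any(grepl("f__FX; g__Unclassified", gen$taxa)))
  # unclassified genus is distinct from the classified ones of the family
  expect_equal(unname(gen$counts[, "k__Bacteria; p__P1; c__C1; o__O1; f__FX; g__Unclassified"]),
               unname(tb$counts[, "o3"]))
  # hierarchy consistency: genus sums within family == family collapse
  fam_from_gen <- sapply(split(seq_along(gen$taxa),
                               sub("; g__.*$", "", gen$taxa)),
                         function(j) rowSums(gen$counts[, j, drop = FALSE]))
  expect_equal(unname(fam_from_gen[, sort(colnames(fam_from_gen))]),
               unname(fam$counts[, sort(fam$taxa)]))
  # empty lineage -> Unassigned bucket
  tb2 <- count_table(matrix(c(1L, 2L), 1, 2,
                            dimnames = list("s1", c("oA", "oB"))),
                     c(oA = "", oB = "k__Bacteria; p__P9"))
  ph <- collapse_taxonomy(tb2, "phylum")
  expect_true("Unassigned" %in% ph$taxa)
})

test_that("two-proportion Z tests match an exact-test oracle and Bonferroni count", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:40),
                   grp = rep(c("A", "B"), each = 20),
                   diet = c(rep("veg", 10), rep("omni", 10),
                            rep("veg", 10), rep("omni", 10)))
  res <- compare_factor_proportions(md, "diet", setNames(md$grp, md$sample_id))
  expect_equal(res$z[res$level == "veg"], 0)
  expect_equal(res$p[res$level == "veg"], 1)

  md2 <- data.frame(sample_id = sprintf("s%02d", 1:40),
                    grp = rep(c("A", "B"), each = 20),
                    diet = c(rep("veg", 18), rep("omni", 2),
                             rep("veg", 2), rep("omni", 18)))
  res2 <- compare_factor_proportions(md2, "diet", setNames(md2$grp, md2$sample_id))
  expect_lt(res2$p[res2$level == "veg"], 0.001)
  # exact binomial enumeration oracle for the same 2x2 table
  expect_lt(fisher.test(matrix(c(18, 2, 2, 18), 2))$p.value, 0.001)

  # 4 groups -> 6 pairs -> p_bonf = min(1, 6p)
  md3 <- data.frame(sample_id = sprintf("s%02d", 1:40),
                    grp = rep(c("A", "B", "C", "D"), each = 10),
                    diet = rep(c("veg", "omni"), 20))
  res3 <- compare_factor_proportions(md3, "diet", setNames(md3$grp, md3$sample_id))
  expect_equal(res3$p_bonf, pmin(1, res3$p * 6))
})
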