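#' Quality-control configuration
#'
#' Defaults reproduce the study window: adults (18-55 y), plausible BMI
#' (10-60 kg/m2), fecal samples collected in the USA, OTUs with at least 10
#' reads overall and samples with at least 1,000 reads.
#'
#' @param bmi_min,bmi_max BMI window (kg/m2), exclusive bounds violated.
#' @param age_min,age_max age window (years).
#' @param required_site accepted body sites.
#' @param required_country accepted countries (metadata encodings vary, so
#'   this is a set).
#' @param known_ethnicities ethnicity labels treated as declared.
#' @param min_otu_total minimum total reads for an OTU to be kept.
#' @param min_sample_depth minimum per-sample read total.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(bmi_min = 10, bmi_max = 60,
                      age_min = 18, age_max = 55,
                      required_site = "fecal",
                      required_country = "USA",
                      known_ethnicities = c("African American",
                                            "Asian-Pacific Islander",
                                            "Caucasian", "Hispanic"),
                      min_otu_total = 10, min_sample_depth = 1000) {
  stopifnot(bmi_min < bmi_max, age_min < age_max,
            min_otu_total >= 0, min_sample_depth >= 1)
  structure(list(bmi_min = bmi_min, bmi_max = bmi_max,
                 age_min = age_min, age_max = age_max,
                 required_site = required_site,
                 required_country = required_country,
                 known_ethnicities = known_ethnicities,
                 min_otu_total = min_otu_total,
                 min_sample_depth = min_sample_depth),
            class = "qc_config")
}

#' Apply cohort quality control
#'
#' Filters samples and OTUs in a fixed order so the per-step attrition
#' report is comparable across data sets: BMI range, age present and in
#' range, sample present in the metadata mapping, declared ethnicity,
#' fecal origin, declared sex, country, then OTUs with fewer than
#' `min_otu_total` reads and samples below `min_sample_depth`.  A sample
#' failing several filters is attributed to the first failing step.
#'
#' @param table a [count_table()].
#' @param metadata data.frame with `sample_id`, `ethnicity`, `sex`, `age`,
#'   `bmi`, `body_site`, `country`.
#' @param config a [qc_config()].
#' @return list with the filtered `table`, matching `metadata` (row order of
#'   the table), and `report`: a data.frame of per-step removals.
#' @export
apply_qc <- function(table, metadata, config = qc_config()) {
  stopifnot(inherits(table, "count_table"), inherits(config, "qc_config"))
  md <- metadata[match(intersect(table$sample_ids, metadata$sample_id),
                       metadata$sample_id), , drop = FALSE]
  keep <- table$sample_ids
  report <- data.frame(step = character(), removed = integer(),
                       remaining = integer(), stringsAsFactors = FALSE)
  drop_step <- function(keep, bad_ids, step) {
    bad <- intersect(keep, bad_ids)
    report <<- rbind(report, data.frame(step = step, removed = length(bad),
                                        remaining = length(keep) - length(bad)))
    setdiff(keep, bad)
  }
  col <- function(name) {
    if (name %in% names(metadata)) metadata[[name]][match(keep, metadata$sample_id)]
    else rep(NA, length(keep))
  }

  bmi <- col("bmi")
  keep <- drop_step(keep, keep[!is.na(bmi) & bmi > config$bmi_max], "bmi_high")
  bmi <- col("bmi")
  keep <- drop_step(keep, keep[!is.na(bmi) & bmi < config$bmi_min], "bmi_low")
  age <- col("age")
  keep <- drop_step(keep, keep[is.na(age)], "age_missing")
  age <- col("age")
  keep <- drop_step(keep, keep[age > config$age_max], "age_high")
  age <- col("age")
  keep <- drop_step(keep, keep[age < config$age_min], "age_low")
  keep <- drop_step(keep, setdiff(keep, metadata$sample_id), "not_in_mapping")
  eth <- col("ethnicity")
  keep <- drop_step(keep, keep[is.na(eth) | !(eth %in% config$known_ethnicities)],
                    "ethnicity_unknown")
  site <- col("body_site")
  keep <- drop_step(keep, keep[is.na(site) | !(site %in% config$required_site)],
                    "not_fecal")
  sex <- col("sex")
  keep <- drop_step(keep, keep[is.na(sex) | !(sex %in% c("male", "female"))],
                    "sex_unknown")
  ctry <- col("country")
  keep <- drop_step(keep, keep[is.na(ctry) | !(ctry %in% config$required_country)],
                    "country")

  if (length(keep) == 0) stop("all samples removed by quality control")
  counts <- table$counts[keep, , drop = FALSE]
  otu_keep <- colnames(counts)[colSums(counts) >= config$min_otu_total]
  report <- rbind(report, data.frame(step = "otu_min_total",
                                     removed = ncol(counts) - length(otu_keep),
                                     remaining = length(keep)))
  counts <- counts[, otu_keep, drop = FALSE]
  deep <- rownames(counts)[rowSums(counts) >= config$min_sample_depth]
  report <- rbind(report, data.frame(step = "sample_min_depth",
                                     removed = nrow(counts) - length(deep),
                                     remaining = length(deep)))
  if (length(deep) == 0) stop("all samples removed by quality control")
  out_table <- count_table(counts[deep, , drop = FALSE], table$taxonomy[otu_keep])
  out_md <- metadata[match(deep, metadata$sample_id), , drop = FALSE]
  rownames(out_md) <- NULL
  list(table = out_table, metadata = out_md, report = report)
}

#' Pairwise two-proportion Z tests of a categorical factor across groups
#'
#' For each level of `factor` and each pair of groups, tests whether the
#' proportion of samples carrying that level differs between the groups
#' (pooled-variance two-proportion Z).  P-values are Bonferroni corrected
#' within the factor for the number of pairwise group comparisons, mirroring
#' structured-metadata screening across cohort demographics.
#'
#' @param metadata data.frame with `sample_id` and the factor column.
#' @param factor name of the categorical column to test.
#' @param groups named group labels (by sample id) defining the comparison
#'   groups, or the name of a metadata column.
#' @return data.frame: level, group pair, counts, z, p, p_bonf.
#' @export
compare_factor_proportions <- function(metadata, factor, groups) {
  if (is.character(groups) && length(groups) == 1L) {
    groups <- setNames(metadata[[groups]], metadata$sample_id)
  }
  groups <- groups[metadata$sample_id]
  vals <- metadata[[factor]]
  ok <- !is.na(vals) & !is.na(groups)
  vals <- as.character(vals[ok]); grp <- as.character(groups[ok])
  glev <- sort(unique(grp))
  pairs <- if (length(glev) >= 2) combn(glev, 2, simplify = FALSE) else list()
  n_pairs <- length(pairs)
  rows <- list()
  for (lev in sort(unique(vals))) {
    for (pr in pairs) {
      nA <- sum(grp == pr[1]); nB <- sum(grp == pr[2])
      if (nA == 0 || nB == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          level = lev, group_a = pr[1], group_b = pr[2], x_a = NA, n_a = nA,
          x_b = NA, n_b = nB, z = NA, p = NA, p_bonf = NA, skipped = TRUE)
        next
      }
      xA <- sum(grp == pr[1] & vals == lev)
      xB <- sum(grp == pr[2] & vals == lev)
      p_pool <- (xA + xB) / (nA + nB)
      se <- sqrt(p_pool * (1 - p_pool) * (1 / nA + 1 / nB))
      z <- if (se == 0) 0 else (xA / nA - xB / nB) / se
      p <- 2 * pnorm(-abs(z))
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, group_a = pr[1], group_b = pr[2], x_a = xA, n_a = nA,
        x_b = xB, n_b = nB, z = z, p = p,
        p_bonf = min(1, p * n_pairs), skipped = FALSE)
    }
  }
  do.call(rbind, rows)
}
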