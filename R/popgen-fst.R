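#' Per-population allele frequencies
#'
#' Alternate-allele frequency per variant (alt dosage sum over twice the
#' called diploids), per population or overall, plus the global minor
#' allele frequency and the standard MAF < `maf_min` exclusion flag.
#' Missing genotypes are excluded per variant (complete-case within
#' population).
#'
#' @param panel a `variant_panel`.
#' @param population population label, or `NULL` for the whole panel.
#' @param maf_min exclusion threshold on global MAF.
#' @return data.frame: id, alt_freq, maf, n_called, exclude_maf.
#' @export
allele_frequencies <- function(panel, population = NULL, maf_min = 0.01) {
  geno <- panel$genotypes
  if (!is.null(population)) {
    if (!population %in% panel$populations)
      stop("unknown population: ", population)
    geno <- geno[, panel$populations == population, drop = FALSE]
  }
  called <- rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE)
  freq <- ifelse(called > 0, alt / (2 * called), NA)
  # global MAF always computed on the full panel
  all_called <- rowSums(!is.na(panel$genotypes))
  all_freq <- ifelse(all_called > 0,
                     rowSums(panel$genotypes, na.rm = TRUE) / (2 * all_called),
                     NA)
  maf <- pmin(all_freq, 1 - all_freq)
  data.frame(id = rownames(geno), alt_freq = freq, maf = maf,
             n_called = called,
             exclude_maf = !is.na(maf) & maf < maf_min,
             stringsAsFactors = FALSE)
}

# Vectorised Weir & Cockerham (1984) two-population per-variant estimator:
# theta = a / (a + b + c) from the among-population (a), among-individual
# (b) and within-individual (c) variance components, using observed
# heterozygosity.  Negative estimates are reported as computed.
wc_fst_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham FST between two populations
#'
#' Per-variant Weir & Cockerham (1984) ratio-of-variance-components
#' estimator from genotype counts (the per-site estimator of the standard
#' VCF tooling).  Variants monomorphic in both populations, or with fewer
#' than two called diploids in either, are returned as `NA` with a skip
#' flag.  Estimates are symmetric in the population order and may be
#' negative.
#'
#' @param panel a `variant_panel`.
#' @param popA,popB population labels.
#' @param variants variant ids (default all).
#' @return data.frame: id, fst, n_a, n_b, skipped.
#' @export
weir_cockerham_fst <- function(panel, popA, popB, variants = NULL) {
  for (p in c(popA, popB))
    if (!p %in% panel$populations) stop("unknown population: ", p)
  geno <- panel$genotypes
  variants <- variants %||% rownames(geno)
  ga <- geno[variants, panel$populations == popA, drop = FALSE]
  gb <- geno[variants, panel$populations == popB, drop = FALSE]
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- rowSums(ga == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- rowSums(gb == 1L, na.rm = TRUE) / pmax(n2, 1)
  comp <- wc_fst_components(n1, n2, p1, p2, h1, h2)
  denom <- comp$a + comp$b + comp$c
  mono <- (p1 %in% c(0, 1)) & (p2 %in% c(0, 1)) & (p1 == p2)
  bad <- n1 < 2 | n2 < 2 | mono | denom == 0
  fst <- ifelse(bad, NA_real_, comp$a / denom)
  data.frame(id = variants, fst = fst, n_a = n1, n_b = n2,
             a = comp$a, b = comp$b, c = comp$c,
             skipped = bad, stringsAsFactors = FALSE)
}

#' Multi-locus weighted Weir-Cockerham FST
#'
#' The ratio-of-sums estimator `sum(a) / sum(a + b + c)` over variants
#' (the Weir-Cockerham recommendation for combining loci; the per-site
#' average is biased downward when each site's among-population variance
#' has a single degree of freedom).
#'
#' @param fst_records output of [weir_cockerham_fst()].
#' @return single numeric FST estimate.
#' @export
fst_weighted_mean <- function(fst_records) {
  ok <- !fst_records$skipped
  sum(fst_records$a[ok]) / sum((fst_records$a + fst_records$b +
                                  fst_records$c)[ok])
}

#' Percentile ranks of FST values against a background
#'
#' Percentile = `100 * (1 - higher / total)` where `higher` counts
#' background variants with STRICTLY larger FST (ties do not count
#' against the target).  Flags mark the >= 95th and >= 99th percentiles;
#' backgrounds smaller than 20 variants are marked low-confidence.
#'
#' @param target_fst numeric FST values to rank.
#' @param background_fst background FST values (NA dropped).
#' @return data.frame: fst, higher, total, percentile, above_95, above_99,
#'   low_confidence.
#' @export
fst_percentiles <- function(target_fst, background_fst) {
  bg <- background_fst[!is.na(background_fst)]
  if (length(bg) == 0) stop("empty FST background")
  higher <- vapply(target_fst, function(v)
    if (is.na(v)) NA_integer_ else sum(bg > v), integer(1))
  pct <- 100 * (1 - higher / length(bg))
  data.frame(fst = target_fst, higher = higher, total = length(bg),
             percentile = pct,
             above_95 = !is.na(pct) & pct >= 95,
             above_99 = !is.na(pct) & pct >= 99,
             low_confidence = length(bg) < 20)
}

#' Pairwise-population FST scan with percentile outlier flags
#'
#' For every requested population pair: per-variant Weir-Cockerham FST
#' (after the global MAF filter), ranked against all variants on the same
#' chromosome and against all variants genome-wide for that pair.
#'
#' @param panel a `variant_panel`.
#' @param pairs list of 2-vectors of population labels (default: all
#'   pairs).
#' @param exclude_pairs list of pairs to drop (order-insensitive), e.g.
#'   population pairs whose comparison is not of interest.
#' @param maf_min global MAF exclusion threshold.
#' @return data.frame of `fst_record`s: id, chrom, pop_a, pop_b, fst,
#'   chrom higher/total/percentile, genome higher/total/percentile,
#'   above_95, above_99 (either background at/above the threshold).
#' @export
fst_scan <- function(panel, pairs = NULL, exclude_pairs = NULL,
                     maf_min = 0.01) {
  pops <- sort(unique(panel$populations))
  pairs <- pairs %||% combn(pops, 2, simplify = FALSE)
  if (!is.null(exclude_pairs)) {
    keys <- vapply(exclude_pairs, function(p) paste(sort(p), collapse = "|"),
                   character(1))
    pairs <- Filter(function(p)
      !(paste(sort(p), collapse = "|") %in% keys), pairs)
  }
  if (length(pairs) == 0) {
    return(data.frame(id = character(), chrom = character(),
                      pop_a = character(), pop_b = character(), fst = numeric(),
                      chrom_higher = integer(), chrom_total = integer(),
                      chrom_percentile = numeric(), genome_higher = integer(),
                      genome_total = integer(), genome_percentile = numeric(),
                      above_95 = logical(), above_99 = logical()))
  }
  af <- allele_frequencies(panel, maf_min = maf_min)
  use <- af$id[!af$exclude_maf]
  chrom <- setNames(panel$variants$chrom, panel$variants$id)
  out <- list()
  for (pr in pairs) {
    rec <- weir_cockerham_fst(panel, pr[1], pr[2], variants = use)
    rec <- rec[!rec$skipped, ]
    gp <- fst_percentiles(rec$fst, rec$fst)
    rec$genome_higher <- gp$higher
    rec$genome_total <- gp$total
    rec$genome_percentile <- gp$percentile
    rec$chrom <- chrom[rec$id]
    rec$chrom_higher <- NA_integer_
    rec$chrom_total <- NA_integer_
    rec$chrom_percentile <- NA_real_
    for (ch in unique(rec$chrom)) {
      sel <- rec$chrom == ch
      cp <- fst_percentiles(rec$fst[sel], rec$fst[sel])
      rec$chrom_higher[sel] <- cp$higher
      rec$chrom_total[sel] <- cp$total
      rec$chrom_percentile[sel] <- cp$percentile
    }
    rec$above_95 <- rec$genome_percentile >= 95 | rec$chrom_percentile >= 95
    rec$above_99 <- rec$genome_percentile >= 99 | rec$chrom_percentile >= 99
    rec$pop_a <- pr[1]; rec$pop_b <- pr[2]
    out[[paste(pr, collapse = "|")]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("id", "chrom", "pop_a", "pop_b", "fst",
          "chrom_higher", "chrom_total", "chrom_percentile",
          "genome_higher", "genome_total", "genome_percentile",
          "above_95", "above_99")]
}
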