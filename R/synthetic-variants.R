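#' Variant panel configuration
#'
#' Parameters for a Balding-Nichols panel: per-population allele
#' frequencies are beta-distributed around a shared ancestral frequency
#' with differentiation parameter F; diploid genotypes are binomial draws.
#' A tail of outlier variants uses a larger F, for exercising percentile
#' outlier flagging.
#'
#' @param seed RNG seed.
#' @param n_variants number of variants.
#' @param n_populations number of populations.
#' @param samples_per_population diploids per population (>= 2; pairwise
#'   FST is undefined below that).
#' @param differentiation background Balding-Nichols F in `[0, 1)`.
#' @param n_outlier_variants how many trailing variants are outliers.
#' @param outlier_differentiation F for outlier variants; must exceed
#'   `differentiation` when outliers are requested.
#' @param n_chromosomes chromosomes the variants are spread over.
#' @return list of class `variant_panel_config`.
#' @export
variant_panel_config <- function(seed, n_variants = 1000, n_populations = 2,
                                 samples_per_population = 100,
                                 differentiation = 0.1,
                                 n_outlier_variants = 0,
                                 outlier_differentiation = 0.5,
                                 n_chromosomes = 4) {
  stopifnot(n_variants >= 1, n_populations >= 2,
            differentiation >= 0, differentiation < 1,
            outlier_differentiation >= 0, outlier_differentiation < 1)
  if (samples_per_population < 2)
    stop("samples_per_population must be >= 2 (FST undefined otherwise)")
  if (n_outlier_variants > 0 && outlier_differentiation <= differentiation)
    stop("outlier_differentiation must exceed differentiation")
  structure(list(seed = seed, n_variants = n_variants,
                 n_populations = n_populations,
                 samples_per_population = samples_per_population,
                 differentiation = differentiation,
                 n_outlier_variants = n_outlier_variants,
                 outlier_differentiation = outlier_differentiation,
                 n_chromosomes = n_chromosomes),
            class = "variant_panel_config")
}

#' Generate a Balding-Nichols variant panel
#'
#' Ancestral frequencies are uniform on (0.05, 0.95).  With F = 0 the
#' population frequencies equal the ancestral frequency exactly; otherwise
#' they are Beta(p(1-F)/F, (1-p)(1-F)/F) draws per population.  Outlier
#' variants (the last `n_outlier_variants`) are constructed rather than
#' drawn: mid-range ancestral frequency and deterministic alternating
#' divergence `p +/- sqrt(F p(1-p))`, which matches the Balding-Nichols
#' among-population frequency variance at the outlier F while guaranteeing
#' every outlier realises its target differentiation (beta draws at high F
#' occasionally coincide by chance, which would defeat their purpose as
#' planted percentile outliers).
#'
#' @param config a [variant_panel_config()].
#' @return Object of class `variant_panel`: `variants` (data.frame id,
#'   chrom, pos, ref, alt, is_outlier), `genotypes` (variants x samples
#'   alt-dosage matrix, 0/1/2 or NA), `populations` (named vector
#'   sample -> population).
#' @export
generate_variant_panel <- function(config) {
  stopifnot(inherits(config, "variant_panel_config"))
  with_seed(config$seed, {
    nv <- config$n_variants
    np <- config$n_populations
    ns <- config$samples_per_population
    f_vec <- rep(config$differentiation, nv)
    outlier <- rep(FALSE, nv)
    if (config$n_outlier_variants > 0) {
      idx <- seq(nv - config$n_outlier_variants + 1L, nv)
      f_vec[idx] <- config$outlier_differentiation
      outlier[idx] <- TRUE
    }
    anc <- runif(nv, 0.05, 0.95)
    pops <- paste0("POP", seq_len(np))
    samples <- as.vector(vapply(pops, function(p)
      sprintf("%s_S%03d", p, seq_len(ns)), character(ns)))
    pop_of <- setNames(rep(pops, each = ns), samples)
    geno <- matrix(NA_integer_, nv, np * ns,
                   dimnames = list(sprintf("var%05d", seq_len(nv)), samples))
    anc[outlier] <- runif(sum(outlier), 0.4, 0.6)
    for (k in seq_len(np)) {
      pk <- ifelse(f_vec == 0, anc,
                   rbeta(nv, anc * (1 - f_vec) / pmax(f_vec, 1e-12),
                         (1 - anc) * (1 - f_vec) / pmax(f_vec, 1e-12)))
      pk[f_vec == 0] <- anc[f_vec == 0]
      # outliers are constructed, not drawn: deterministic divergence with
      # among-population frequency variance F * p(1-p), alternating sign,
      # so every outlier realises its target differentiation
      sgn <- if (k %% 2L == 1L) 1 else -1
      pk[outlier] <- pmin(0.99, pmax(0.01, anc[outlier] +
        sgn * sqrt(f_vec[outlier] * anc[outlier] * (1 - anc[outlier]))))
      cols <- ((k - 1L) * ns + 1L):(k * ns)
      geno[, cols] <- matrix(rbinom(nv * ns, 2L, rep(pk, ns)), nv, ns)
    }
    variants <- data.frame(
      id = rownames(geno),
      chrom = paste0("chr", (seq_len(nv) - 1L) %% config$n_chromosomes + 1L),
      pos = 1000L * seq_len(nv),
      ref = "A", alt = "G", is_outlier = outlier,
      stringsAsFactors = FALSE)
    structure(list(variants = variants, genotypes = geno,
                   populations = pop_of),
              class = "variant_panel")
  })
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("<variant_panel> ", nrow(x$variants), " variants x ",
      ncol(x$genotypes), " samples in ",
      length(unique(x$populations)), " populations\n", sep = "")
  invisible(x)
}

#' Write a variant panel as a minimal VCF plus a population map
#'
#' GT-only VCF (v4.2) and a two-column tab-delimited sample/population map,
#' readable back with [read_variant_panel()].
#'
#' @param panel a `variant_panel`.
#' @param vcf_path,popmap_path output files.
#' @export
write_variant_panel <- function(panel, vcf_path, popmap_path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(panel$genotypes)),
                     collapse = "\t")), con)
  gt <- matrix(gt_code[as.character(panel$genotypes)],
               nrow = nrow(panel$genotypes))
  gt[is.na(gt)] <- "./."
  v <- panel$variants
  writeLines(paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t"), con)
  write.table(data.frame(sample = names(panel$populations),
                         population = unname(panel$populations)),
              popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Read a variant panel from VCF + population map
#'
#' @param vcf_path VCF with GT genotypes (parsed via \pkg{vcfR}).
#' @param popmap_path two-column tab-delimited sample/population table.
#' @return a `variant_panel`.
#' @export
read_variant_panel <- function(vcf_path, popmap_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         is_outlier = NA, stringsAsFactors = FALSE)
  rownames(dosage) <- variants$id
  pm <- read.table(popmap_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  pops <- setNames(pm[[2]], pm[[1]])
  if (!all(colnames(dosage) %in% names(pops)))
    stop("population map does not cover all VCF samples")
  structure(list(variants = variants, genotypes = dosage,
                 populations = pops[colnames(dosage)]),
            class = "variant_panel")
}
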