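#' Planted taxon effect
#'
#' Describes a group-specific perturbation of one taxon in a synthetic
#' cohort.  `fold_change` is the fold *reduction* of the taxon's expected
#' relative abundance in the affected group (the motivating observation is
#' an eight-fold reduction of Christensenellaceae in one group):
#' `fold_change = 8` makes the affected group's expectation one eighth of
#' the other groups'.  `presence_shift` additively changes the carriage
#' probability in the affected group.  `fold_change = 1` and
#' `presence_shift = 0` is a null effect.
#'
#' @param taxon_id an OTU id (e.g. `"OTU_0001"`) or a taxonomy fragment
#'   (e.g. `"f__F01"`); fragments match every OTU whose lineage contains
#'   them, so family-level effects are planted on all member OTUs.
#' @param affected_group group label the effect applies to.
#' @param fold_change positive fold reduction in the affected group.
#' @param presence_shift additive change to carriage probability, in
#'   `[-1, 1]`.
#' @return list of class `planted_effect`.
#' @export
planted_effect <- function(taxon_id, affected_group, fold_change = 1,
                           presence_shift = 0) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L,
            fold_change > 0, presence_shift >= -1, presence_shift <= 1)
  structure(list(taxon_id = taxon_id, affected_group = affected_group,
                 fold_change = fold_change, presence_shift = presence_shift),
            class = "planted_effect")
}

#' Synthetic cohort configuration
#'
#' Defines a 16S-like cohort: per-group sample counts, a log-normal base
#' composition, Dirichlet-multinomial counts with variable sequencing
#' depth, per-(sample, taxon) zero inflation, optional planted group
#' effects, covariate effects on selected taxa, and a block of co-occurring
#' families driven by a shared latent factor.  Defaults mirror the cohort
#' structure the pipeline targets: four groups with severe class imbalance
#' (~90% majority), adult covariates inside the QC window (age U[18,55],
#' BMI N(25, 4) truncated to (10, 60), sex Bernoulli(0.5)).
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical cohorts.
#' @param n_samples_per_group named integer vector, group label -> count.
#' @param n_otus number of OTUs.
#' @param depth_range integer `(min, max)` read depth, drawn uniformly per
#'   sample; `min >= 1`.
#' @param base_abundance_logmean_sd `(meanlog, sdlog)` of the log-normal
#'   base profile.
#' @param planted_taxa list of [planted_effect()]s.
#' @param covariate_effects list of `list(covariate=, taxon_id=, effect=)`
#'   entries; `effect` is log-fold change per unit of the (centred)
#'   covariate.
#' @param cooccurrence_block `list(n_families=, correlation=)`: the first
#'   `n_families` families share a latent log-normal factor whose strength
#'   scales with `correlation` in `[0, 1]`.
#' @param zero_inflation probability in `[0, 1)` that a (sample, taxon)
#'   expectation is zeroed before renormalisation (carriage differences).
#' @param overdispersion Dirichlet concentration; smaller is more
#'   overdispersed than a plain multinomial.
#' @param n_families number of families in the generated taxonomy.
#' @param id_prefix sample-id prefix, to keep paired cohorts distinct.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_samples_per_group = c("African American" = 13,
                                                      "Asian-Pacific Islander" = 88,
                                                      "Caucasian" = 1237,
                                                      "Hispanic" = 37),
                              n_otus = 200,
                              depth_range = c(1000, 10000),
                              base_abundance_logmean_sd = c(0, 1.5),
                              planted_taxa = list(),
                              covariate_effects = list(),
                              cooccurrence_block = list(n_families = 0,
                                                        correlation = 0.8),
                              zero_inflation = 0.15,
                              overdispersion = 200,
                              n_families = 25,
                              id_prefix = "S") {
  if (is.null(names(n_samples_per_group)) || any(!nzchar(names(n_samples_per_group))))
    stop("n_samples_per_group must be named by group label")
  if (any(n_samples_per_group <= 0)) stop("group sizes must be positive")
  stopifnot(n_otus >= 1, length(depth_range) == 2, depth_range[1] >= 1,
            depth_range[1] <= depth_range[2],
            zero_inflation >= 0, zero_inflation < 1,
            overdispersion > 0, n_families >= 1)
  cb <- modifyList(list(n_families = 0, correlation = 0.8), cooccurrence_block)
  stopifnot(cb$correlation >= 0, cb$correlation <= 1)
  structure(list(seed = seed,
                 n_samples_per_group = n_samples_per_group,
                 n_otus = n_otus, depth_range = depth_range,
                 base_abundance_logmean_sd = base_abundance_logmean_sd,
                 planted_taxa = planted_taxa,
                 covariate_effects = covariate_effects,
                 cooccurrence_block = cb,
                 zero_inflation = zero_inflation,
                 overdispersion = overdispersion,
                 n_families = n_families,
                 id_prefix = id_prefix),
            class = "simulation_config")
}

# Deterministic 7-rank taxonomy shared by all cohorts of the same shape:
# OTU i belongs to family F{(i-1) %% n_families + 1}; every third genus
# within a family is left unclassified ("g__") to exercise the
# unclassified-rank handling downstream.
synthetic_taxonomy <- function(n_otus, n_families) {
  fam <- (seq_len(n_otus) - 1L) %% n_families + 1L
  gen_idx <- (seq_len(n_otus) - 1L) %/% n_families %% 3L + 1L
  phy <- (fam - 1L) %/% 8L + 1L
  g <- ifelse(gen_idx == 3L, "g__",
              sprintf("g__G%02d_%d", fam, gen_idx))
  tax <- sprintf("k__Bacteria; p__P%02d; c__C%02d; o__O%02d; f__F%02d; %s",
                 phy, phy, fam, fam, g)
  setNames(tax, sprintf("OTU_%04d", seq_len(n_otus)))
}

# OTU indices matched by a planted-effect taxon id (OTU id or lineage
# fragment); errors if nothing matches.
match_planted <- function(taxon_id, taxonomy) {
  ids <- names(taxonomy)
  if (taxon_id %in% ids) return(match(taxon_id, ids))
  hits <- which(grepl(taxon_id, taxonomy, fixed = TRUE))
  if (length(hits) == 0)
    stop("planted taxon id '", taxon_id, "' matches no OTU")
  hits
}

#' Generate a synthetic cohort
#'
#' Draws one sample per requested individual.  Expected compositions start
#' from the log-normal base profile, are modified by planted effects for
#' the sample's group and by covariate effects, multiplied by the
#' co-occurrence latent factor, zero-inflated, renormalised, and fed to a
#' Dirichlet-multinomial at the sample's depth.  Taxa carrying planted
#' effects have their baseline raised to at least the 75th percentile of
#' the profile so planted signals are identifiable at realistic depths.
#'
#' @param config a [simulation_config()].
#' @return list with `table` (a [count_table()]) and `metadata`
#'   (data.frame: sample_id, ethnicity, sex, age, bmi, body_site, country).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n_otus <- config$n_otus
    taxonomy <- synthetic_taxonomy(n_otus, config$n_families)
    groups <- rep(names(config$n_samples_per_group), config$n_samples_per_group)
    n <- length(groups)
    ids <- sprintf("%s_%04d", config$id_prefix, seq_len(n))

    base <- rlnorm(n_otus, config$base_abundance_logmean_sd[1],
                   config$base_abundance_logmean_sd[2])
    planted_idx <- lapply(config$planted_taxa, function(e)
      match_planted(e$taxon_id, taxonomy))
    if (length(planted_idx) > 0) {
      floor_val <- quantile(base, 0.75)
      all_idx <- unique(unlist(planted_idx))
      base[all_idx] <- pmax(base[all_idx], floor_val)
    }

    age <- runif(n, 18, 55)
    bmi <- pmin(pmax(rnorm(n, 25, 4), 10.01), 59.99)
    sex <- ifelse(runif(n) < 0.5, "female", "male")
    cov_values <- list(age = age - mean(age), bmi = bmi - mean(bmi),
                       sex = as.numeric(sex == "male") - 0.5)

    cb <- config$cooccurrence_block
    block_otus <- integer(0)
    if (cb$n_families > 0) {
      fam <- (seq_len(n_otus) - 1L) %% config$n_families + 1L
      block_otus <- which(fam <= cb$n_families)
    }
    latent <- rnorm(n)
    block_sigma <- 1.5 * cb$correlation

    depths <- if (config$depth_range[1] == config$depth_range[2])
      rep(config$depth_range[1], n)
    else sample(config$depth_range[1]:config$depth_range[2], n, replace = TRUE)

    counts <- matrix(0L, n, n_otus, dimnames = list(ids, names(taxonomy)))
    for (i in seq_len(n)) {
      m <- base
      carriage <- rep(1 - config$zero_inflation, n_otus)
      for (k in seq_along(config$planted_taxa)) {
        e <- config$planted_taxa[[k]]
        if (identical(e$affected_group, groups[i])) {
          m[planted_idx[[k]]] <- m[planted_idx[[k]]] / e$fold_change
          carriage[planted_idx[[k]]] <-
            pmin(1, pmax(0, carriage[planted_idx[[k]]] + e$presence_shift))
        }
      }
      for (ce in config$covariate_effects) {
        j <- match_planted(ce$taxon_id, taxonomy)
        m[j] <- m[j] * exp(ce$effect * cov_values[[ce$covariate]][i])
      }
      if (length(block_otus) > 0)
        m[block_otus] <- m[block_otus] * exp(block_sigma * latent[i])
      present <- runif(n_otus) < carriage
      m[!present] <- 0
      if (all(m == 0)) m[which.max(base)] <- base[which.max(base)]
      alpha <- config$overdispersion * m / sum(m)
      g <- rgamma(n_otus, shape = alpha)
      g[alpha == 0] <- 0
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      counts[i, ] <- as.integer(rmultinom(1, depths[i], g / sum(g)))
    }

    metadata <- data.frame(sample_id = ids, ethnicity = groups, sex = sex,
                           age = age, bmi = bmi, body_site = "fecal",
                           country = "USA", stringsAsFactors = FALSE)
    list(table = count_table(counts, taxonomy), metadata = metadata)
  })
}

#' Generate two cohorts sharing planted effects
#'
#' Emulates a two-cohort replication design: both cohorts carry
#' `shared_taxa` effects on the same taxonomy strings, while base profiles,
#' noise and cohort-specific effects stay independent (distinct seeds).
#'
#' @param configA,configB [simulation_config()]s; their taxonomies must
#'   resolve every shared taxon id.
#' @param shared_taxa list of [planted_effect()]s planted in both cohorts.
#' @return list with elements `A` and `B`, each as [generate_cohort()].
#' @export
generate_paired_cohorts <- function(configA, configB, shared_taxa = list()) {
  add_shared <- function(config) {
    for (e in shared_taxa) {
      clash <- vapply(config$planted_taxa, function(x)
        identical(x$taxon_id, e$taxon_id) &&
          identical(x$affected_group, e$affected_group), logical(1))
      if (any(clash))
        stop("conflicting planted effects on '", e$taxon_id,
             "' for group '", e$affected_group, "'")
    }
    config$planted_taxa <- c(config$planted_taxa, shared_taxa)
    config
  }
  list(A = generate_cohort(add_shared(configA)),
       B = generate_cohort(add_shared(configB)))
}
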