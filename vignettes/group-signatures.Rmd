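---
title: "Detecting reproducible group-associated signatures in 16S cohorts"
author: "cohortsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reproducible group-associated signatures in 16S cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortsig)
```

## The problem

Does a categorical host factor -- the motivating case is self-declared
ethnicity in US gut-microbiota surveys -- leave a detectable, *reproducible*
imprint on 16S community profiles?  Community-level effects of such factors
are typically tiny next to inter-individual variation, so the question
splits into several complementary ones, each with its own statistical
machinery:

1. Is the whole community *distinguishable* between groups (ANOSIM,
   PERMANOVA, an adapted BioEnv correlation test)?
2. Are within-group communities more similar than between-group ones
   (intra- vs inter-group beta-diversity contrasts)?
3. Which individual taxa shift, and do the shifts *replicate* in an
   independent cohort (per-taxon Kruskal-Wallis screening with a
   cross-cohort overlap permutation null)?
4. Can group membership be *predicted* from the profile at all
   (one-vs-all random forests under severe class imbalance)?
5. Do the implicated taxa co-occur, and do host variants linked to them
   show unusual population differentiation (family co-occurrence
   clustering; Weir-Cockerham FST percentile ranking)?

`cohortsig` implements this pipeline end to end, together with a
synthetic-data module that generates paired cohorts and variant panels
with the statistical structure the analysis assumes, so every stage is
testable without any external data.  The `analysis/` directory of the
source repository walks the full pipeline over one synthetic study system
in seven numbered stages.

## Quality control and collapsing

`apply_qc()` filters in a fixed, documented order (BMI window 10-60
kg/m^2, age 18-55 y present, sample in the metadata mapping, declared
ethnicity, fecal origin, declared sex, accepted country, OTUs with >= 10
reads, samples with >= 1,000 reads), and reports per-step attrition.  The
order matters only for the report: a sample failing several filters is
charged to the first failing step, which makes attrition tables comparable
across cohorts.  QC is idempotent.

`collapse_taxonomy()` sums OTUs sharing a lineage prefix and closes rows
to relative abundance.  A rank left unclassified (e.g. a bare `g__`)
becomes an `Unclassified` taxon *within its parent*, so unclassified
genera of different families are never merged -- this matches the
convention of genus-level analyses that fall back to the highest
classified level.

## Rarefaction and consensus distances

All distance-based tests operate on *consensus* matrices: the element-wise
mean of (by default) 100 Bray-Curtis matrices, each computed on an
independent rarefaction to even depth (`consensus_distance()`).  Averaging
removes most of the rarefaction noise without the biases of a single
subsample.  Samples below the target depth are dropped, not padded.
Defaults: depths 1,000 and 10,000 reads; 100 rarefactions for beta
consensus and 10 for alpha averaging (the alpha average stabilises much
faster, and 10 keeps the cost linear in metrics x depths).

Shannon diversity is reported in **bits** (log base 2), the convention of
the QIIME-1-era tooling this mirrors; natural-log users should divide by
`log2(e)`.  Chao1 is the bias-corrected form `S + F1(F1-1)/(2(F2+1))`,
with the classical `S + F1^2/(2 F2)` behind a flag.

## Distinguishability tests

`anosim()` is implemented in the package (ranks computed once on the
condensed distances, average ranks for ties,
`R = (mean between - mean within) / (n(n-1)/4)`), because the pipeline
needs an *exhaustive* mode: for small groups all distinct label
assignments are enumerated and the p-value is the exact tail, which is
what the oracle tests compare against.  Monte Carlo p-values use the
never-zero convention `(1 + hits) / (1 + n_perm)`.  The statistic is
cross-checked against `vegan::anosim` in the test suite.

`permanova()` wraps `vegan::adonis2` with sequential (Type-I) sums of
squares in the user's term order -- the formula convention the quoted
model `distance ~ ethnicity + age + sex + bmi` implies -- and averages
per-term statistics over a list of rarefied matrices when supplied.
On 1-D Euclidean data its pseudo-F equals the classical one-way ANOVA F,
which the acceptance suite asserts to 1e-9, along with a 500-simulation
type-I calibration.

`bioenv_adapted()` correlates (Spearman) the community distance vector
with Euclidean distances over an encoded metadata block: continuous
variables centred and scaled, categorical variables full-rank dummy
coded.  Significance for a *target* variable comes from shuffling only
that variable's values across samples and counting how often the shuffled
correlation reaches the observed one.  Shuffling permutes the underlying
category labels, never the dummy columns independently.

Two companion designs probe robustness of ANOSIM to sampling artifacts:
`anosim_subsampled()` repeatedly down-samples over-represented groups to a
common cap and averages R and p; `anosim_ablation()` produces the full
ledger over all groups, each leave-one-out set, and every group pair
(`1 + G + choose(G,2)` entries -- 11 for four groups).

## Taxon-level screening and replication

`kruskal_by_group()` applies the tie-corrected Kruskal-Wallis test per
taxon, with BH-FDR and Bonferroni corrections within one taxonomic rank
and factor (matching per-rank result sheets).  For tiny groups an
exhaustive-enumeration p is available and verified against a brute-force
oracle.

The replication machinery is the scientific heart of the pipeline.
`replication_overlap()` counts identically-labelled taxa FDR-significant
in both cohorts; `overlap_permutation_null()` builds the null by
shuffling group labels *independently in both cohorts* 1,000 times and
recomputing both significant sets and their overlap.  Because ranks and
tie corrections depend only on the data, they are precomputed once and a
permutation costs one group-wise rank-sum per cohort -- that is what makes
1,000 permutations over several ranks affordable in seconds.  Note a
structural property: under the null, both significant sets are almost
always empty, the overlap has an atom at zero, and the permutation
p-value collapses to 1 for most null data sets.  The p-value is therefore
*valid and conservative* rather than uniform, and the test suite asserts
exactly that.

`collapse_redundant_taxa()` applies the 82% rule: a significant genus
carrying at least 82% of its significant parent family's abundance in
every group is the same signal; the genus is kept if classified, the
family if not.  `pairwise_group_shifts()` runs the six pairwise
Mann-Whitney tests per taxon (Bonferroni within taxon and cohort) over
*all* individuals -- zeros are data -- and records both the abundance and
the ubiquity direction, since a shift can be carried by either.
A shift "replicates" when significant in both cohorts with matching
abundance direction.

`abundance_regressions()` fits, per taxon, a linear model of log10
relative abundance among possessors (>= 10 possessors required) and a
logistic model of presence over everyone, each with the group factor
alone and with age, sex and BMI added; the largest group is the dummy
reference.  `presence_phenotype_test()` is the one-tailed carrier test
(possessors have *lower* phenotype), overall and within groups.

## Classification under class imbalance

`rf_one_vs_all()` builds one binary random forest per group against the
pooled rest.  The feature protocol is fixed (`prepare_rf_features()`):
rarefy to 10,000 reads, collapse to genus, drop taxa present in fewer
than `floor(rarest group / 2)` samples, relative abundance, arcsin-sqrt.
Class imbalance is handled by resampling **inside** cross-validation:
each training fold is either downsampled or SMOTE-balanced (synthetic
minority points interpolated between 5-nearest minority neighbours,
combined with majority downsampling to `min(n_maj, 2 n_min)` per class);
the held-out fold is never touched.  This placement is load-bearing:
resampling before the split leaks synthetic neighbours across folds and
manufactures AUC from pure noise.  The test suite contains a deliberately
leaky pipeline and asserts that it inflates AUC while the package's
implementation stays at chance -- the regression test for the single most
common error in imbalanced-data classification.

## Co-occurrence structure

`cooccurrence_clusters()` computes pairwise Spearman correlations between
family abundances, Bonferroni-masks them over all pairs, and extracts
clusters by an explicit rule: average-linkage hierarchical clustering on
`1 - rho` (non-significant edges zeroed), cut at `1 - 0.3`, keeping
groups of >= 3.  The original procedure this formalises was a visual
reading of a clustermap; an explicit rule is reproducible and testable
(the suite plants a 6-family latent-factor block and requires its
recovery).  Non-member families with >= 3 significant positive links into
a cluster are flagged "cluster-associated".  Rank correlation on closed
(compositional) data still carries closure artifacts; Spearman mitigates
the worst linear ones, and the enrichment test (members' external
association p-values vs non-members', one-sided MWU) is rank-based, but
SparCC-style compositional corrections are deliberately out of scope.

## Stability statistics

`ubiquitous_otus()` computes, per group, the set of OTUs present in at
least 50% of samples, each OTU's mean relative abundance over *all* group
samples (zeros included; possessors-only is a flag), and the A/U ratio
(abundance / ubiquity) whose group mean is read as a stability index:
communities whose ubiquitous OTUs are individually low-abundance but
widely shared are more stable.  The within-group regression of log10
abundance on ubiquity is OLS with HC3 heteroscedasticity-robust standard
errors ("robust OLS" is ambiguous; Huber-M is the natural alternative and
the HC3 choice is documented here), Bonferroni-adjusted across groups.

## Population-genetic ranking

`weir_cockerham_fst()` is the Weir & Cockerham (1984) two-population
per-variant ratio-of-variance-components estimator computed from genotype
counts with observed heterozygosity, negative estimates reported as
computed.  Missing genotypes are complete-case within population, and
variants below 1% global MAF are excluded up front.  Two summaries are
exposed: the per-site average and the multi-locus ratio-of-sums
`sum(a)/sum(a+b+c)` (`fst_weighted_mean()`).  With only two populations
each site's among-population variance has a single degree of freedom, so
the per-site average is biased low; the weighted form is the calibrated
estimator (mean within 0.01 of the generating F on Balding-Nichols
panels) and is what the calibration tests assert.

`fst_percentiles()`/`fst_scan()` rank each variant against all variants
on the same chromosome and genome-wide, per population pair, counting
*strictly higher* values (ties do not count against a variant, following
the "number with a higher FST" convention); flags are inclusive at the
95th and 99th percentiles.  Excluded population pairs are configuration,
not code.

## The synthetic-data generator

`generate_cohort()` draws, per sample, a Dirichlet-multinomial count
vector whose expected composition is a log-normal base profile
(`meanlog 0, sdlog 1.5`) modified by planted effects, covariate effects,
a shared latent factor over a co-occurrence block of families, and
per-(sample, taxon) zero inflation (default 0.15) before renormalisation.
Design choices worth stating:

* **Overdispersion** (Dirichlet concentration, default 200) is there
  because real 16S counts are overdispersed relative to a multinomial and
  the rank tests should be exercised under that regime.
* **Planted effects are fold reductions**: `fold_change = 8` divides the
  affected group's expected relative abundance by 8, mirroring the
  observed "eight-fold reduction" phrasing such effects model.  Effects
  act *before* closure, so realised compositional ratios are approximate
  -- tests use tolerance bands (a planted 8-fold reduction realises in
  [6, 10]), never exact ratios.
* **Planted baselines are floored** at the profile's 75th percentile so a
  planted taxon is not accidentally a one-read-per-sample taxon with no
  power at any reasonable depth.
* **Covariates mirror the QC window** (age U[18, 55], BMI N(25, 4)
  truncated to (10, 60), sex Bernoulli(0.5)) so QC passes by
  construction and covariate regressions have realistic ranges.
* The default group sizes reproduce severe class imbalance
  (13 / 88 / 1237 / 37), the regime the imbalance-aware classifiers
  exist for; analyses in this package scale the majority group down
  where full size adds nothing but runtime.

`generate_variant_panel()` draws per-population allele frequencies from
the Balding-Nichols beta around a uniform (0.05, 0.95) ancestral
frequency and genotypes binomially.  Outlier variants are *constructed*,
not drawn: mid-range ancestral frequency and deterministic alternating
divergence `p +/- sqrt(F p (1-p))`, which preserves the Balding-Nichols
among-population variance at the outlier F while guaranteeing that every
planted outlier actually realises high differentiation (independent beta
draws at high F coincide by chance often enough to defeat the purpose of
a planted percentile outlier).

What the generator does **not** emulate: sequencing error and chimeras,
phylogenetic structure (no trees, hence no UniFrac), realistic taxonomic
breadth (a deterministic 25-family scaffold), diet/lifestyle confounding
between groups, or linkage disequilibrium between variants.  Passing
tests therefore demonstrate that the *statistical machinery* is correct
and calibrated under a faithful null and a recoverable alternative -- not
that any real-world cohort difference is of a given size.

## Numerical conventions and degenerate inputs

* Permutation p-values are `(1 + hits)/(1 + n_perm)` everywhere except
  exhaustive enumeration, where the observed assignment is part of the
  enumeration and `p = #(stat* >= stat)/#assignments`.
* Rank ties get average ranks; the Kruskal-Wallis statistic is
  tie-corrected, and a constant taxon is reported as `H = 0, p = 1` with
  a flag rather than `NaN`.
* Mann-Whitney tests use the normal approximation without continuity
  correction, so identical multisets give exactly `p = 1`; exact
  enumeration backs the small-sample oracle tests.
* Distance matrices are validated (symmetry to 1e-8, zero diagonal) and
  symmetrised on construction; all-zero samples are an error naming the
  sample, not a silent NaN.
* Degenerate fits -- constant PERMANOVA terms, constant BioEnv targets,
  all-present or all-absent taxa in the logistic model, monomorphic
  variants -- are flagged and skipped, never imputed.

## Problem sizes used by the test and acceptance suites

The suites favour many small, sharply-posed instances over few large
ones: exhaustive oracles run at n <= 8 (20-70 assignments); calibration
loops use 50-500 replicates of cohorts with 40-80 samples; the planted
replication study runs two cohorts of 600 samples (150 per group) at
depth 10,000 with 1,000 overlap permutations; FST calibration uses 2,000
variants and 100 diploids per population.  These sizes were chosen so the
full suite exercises every calibration claim in a couple of minutes on a
single core while keeping every Monte Carlo band at least ~4 standard
errors wide.

## Known limitations

* Compositionality is handled by rank statistics and documented caveats,
  not by log-ratio or SparCC-style methods; strong planted effects on
  many taxa induce real closure spillover into unplanted taxa (visible in
  the analysis scripts as extra significant families).
* PERMANOVA assumes exchangeability under permutation of raw rows; no
  strata/blocking support.
* The BioEnv adaptation weights dummy columns equally (0/1) against
  scaled continuous variables; other weightings are defensible.
* SMOTE interpolates in the transformed feature space with k = 5; very
  small minorities (< 6) fall back to fewer neighbours or duplication.
* FST percentile backgrounds are the analysed panel itself; with < 20
  background variants percentiles carry a low-confidence flag.
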