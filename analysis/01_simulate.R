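#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# Two paired 16S cohorts ("AGP"-like and "HMP"-like) with four ethnicity
# groups under severe class imbalance, sharing 12 planted family-level
# effects: a six-fold abundance reduction in Asian-Pacific Islanders,
# mirroring the kind of recurrent signature the pipeline is built to
# detect.  Plus a two-population Balding-Nichols variant panel with five
# constructed high-differentiation outliers.  Everything downstream reads
# the plain-text files written here.

suppressMessages(library(cohortsig))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

groups <- c("African American" = 13, "Asian-Pacific Islander" = 60,
            "Caucasian" = 200, "Hispanic" = 37)
planted <- lapply(sprintf("f__F%02d", 1:12), function(f)
  planted_effect(f, "Asian-Pacific Islander", fold_change = 6))

pair <- generate_paired_cohorts(
  simulation_config(seed = 2018L, n_samples_per_group = groups,
                    n_otus = 200, depth_range = c(2000, 15000),
                    cooccurrence_block = list(n_families = 6, correlation = 0.8),
                    id_prefix = "AGP"),
  simulation_config(seed = 2019L, n_samples_per_group = groups,
                    n_otus = 200, depth_range = c(2000, 15000),
                    cooccurrence_block = list(n_families = 6, correlation = 0.8),
                    id_prefix = "HMP"),
  planted)

for (nm in names(pair)) {
  write_classic_otu_table(pair[[nm]]$table,
                          sprintf("results/data/cohort_%s_otus.tsv", nm))
  write_metadata(pair[[nm]]$metadata,
                 sprintf("results/data/cohort_%s_metadata.tsv", nm))
  cat(sprintf("cohort %s: %d samples x %d OTUs, total reads %d\n", nm,
              nrow(pair[[nm]]$table$counts), ncol(pair[[nm]]$table$counts),
              sum(pair[[nm]]$table$counts)))
}

panel <- generate_variant_panel(variant_panel_config(
  seed = 2020L, n_variants = 2000, differentiation = 0.10,
  samples_per_population = 100, n_outlier_variants = 5,
  outlier_differentiation = 0.5))
write_variant_panel(panel, "results/data/panel.vcf",
                    "results/data/panel_popmap.tsv")
cat(sprintf("variant panel: %d variants, %d samples, %d outliers\n",
            nrow(panel$variants), ncol(panel$genotypes),
            sum(panel$variants$is_outlier)))
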