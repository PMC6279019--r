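#!/usr/bin/env Rscript
# Stage 7: per-variant Weir-Cockerham FST between populations with
# chromosome-wide and genome-wide percentile ranks and outlier flags.

suppressMessages(library(cohortsig))

panel <- read_variant_panel("results/data/panel.vcf",
                            "results/data/panel_popmap.tsv")
print(panel)

af <- allele_frequencies(panel)
cat(sprintf("%d/%d variants pass the MAF >= 0.01 filter\n",
            sum(!af$exclude_maf), nrow(af)))

scan <- fst_scan(panel)
fr <- weir_cockerham_fst(panel, "POP1", "POP2")
cat(sprintf("weighted FST = %.4f; per-site mean = %.4f\n",
            fst_weighted_mean(fr), mean(fr$fst, na.rm = TRUE)))
top <- scan[order(-scan$fst), ][1:8, ]
cat("top variants by FST:\n")
print(top[, c("id", "chrom", "fst", "chrom_percentile", "genome_percentile",
              "above_95", "above_99")], row.names = FALSE)
cat(sprintf("%d variants above the 95th percentile, %d above the 99th\n",
            sum(scan$above_95), sum(scan$above_99)))
write.table(scan, "results/fst_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
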