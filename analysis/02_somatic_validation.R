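#!/usr/bin/env Rscript
# Classify candidate SNVs as somatic vs non-validated from the paired
# tumor/normal count tables written by 01_simulate_study.R, and measure
# allele-fraction precision at the heterozygous-SNP panel.

library(poolsnv)

counts <- read_count_table("results/counts.tsv")
panel <- read_site_list("results/panel.tsv", "tsv")
counts <- with_allele_fractions(counts)
thr <- validation_thresholds()  # AF >= 0.1 tumor, < 0.01 normal, depth >= 30

pairs <- list(ALL1 = c("ALL1_gDNA", "Normal1_gDNA"),
              ALL2 = c("ALL2_gDNA", "Normal2_gDNA"),
              ALL1_wga = c("ALL1_wgaDNA", "Normal1_gDNA"),
              ALL2_wga = c("ALL2_wgaDNA", "Normal2_gDNA"))
not_panel <- function(df) {
  df[!(paste(df$chrom, df$pos) %in% paste(panel$chrom, panel$pos)), ]
}
for (nm in names(pairs)) {
  tum <- not_panel(counts[counts$experiment_id == pairs[[nm]][1], ])
  nor <- not_panel(counts[counts$experiment_id == pairs[[nm]][2], ])
  res <- validate_cohort(tum, nor, thr)
  write.table(res$status_table, sprintf("results/validation_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(nm, ": ", res$summary[["somatic"]], " somatic of ",
          sum(res$summary), " candidate sites (",
          res$summary[["insufficient_depth"]], " with insufficient depth)")
}

message("heterozygous-SNP allele-fraction deviation from 0.5:")
for (id in unique(counts$experiment_id)) {
  ec <- counts[counts$experiment_id == id & counts$kind != "pool", ]
  ec <- ec[paste(ec$chrom, ec$pos) %in% paste(panel$chrom, panel$pos) &
             ec$depth >= 30, ]
  if (nrow(ec)) {
    message(sprintf("  %-14s %.4f (n=%d)", id, het_snp_deviation(ec$af),
                    nrow(ec)))
  }
}
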