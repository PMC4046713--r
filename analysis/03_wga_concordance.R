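#!/usr/bin/env Rscript
# Compare whole-genome-amplified DNA against genomic DNA: allele-fraction
# concordance (Pearson r, RMSE) at sites with depth >= 30 in both readouts,
# and coverage evenness (CV, Gini) per experiment.

library(poolsnv)

counts <- with_allele_fractions(read_count_table("results/counts.tsv"))

rows <- list()
for (pid in c("ALL1", "ALL2")) {
  g <- counts[counts$experiment_id == paste0(pid, "_gDNA") &
                counts$depth >= 30, ]
  w <- counts[counts$experiment_id == paste0(pid, "_wgaDNA") &
                counts$depth >= 30, ]
  m <- merge(g[c("chrom", "pos", "af")], w[c("chrom", "pos", "af")],
             by = c("chrom", "pos"), suffixes = c("_gdna", "_wga"))
  cc <- concordance_report(m$af_gdna, m$af_wga)
  rows[[pid]] <- data.frame(patient = pid, pearson_r = cc$pearson_r,
                            rmse = cc$rmse, n_sites = cc$n_sites)
  message(sprintf("%s gDNA vs wgaDNA: r = %.3f, RMSE = %.4f over %d sites",
                  pid, cc$pearson_r, cc$rmse, cc$n_sites))
}
write.table(do.call(rbind, rows), "results/wga_concordance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ev <- do.call(rbind, lapply(split(counts, counts$experiment_id), function(ec) {
  er <- evenness_report(ec$depth)
  data.frame(experiment_id = ec$experiment_id[1], material = ec$material[1],
             cv = er$cv, gini = er$gini, n_sites = er$n_sites)
}))
write.table(ev, "results/evenness.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("depth Gini, gDNA individual experiments: ",
        sprintf("%.3f", mean(ev$gini[ev$material == "gDNA"])))
message("depth Gini, wgaDNA experiments:          ",
        sprintf("%.3f", mean(ev$gini[ev$material == "wgaDNA"])))
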