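#!/usr/bin/env Rscript
# Simulate the default study: two whole-genome-sequenced leukemia patients
# (tumor/normal genomic DNA plus whole-genome-amplified tumor DNA), fourteen
# uncharacterized samples, and non-indexed pools of 2/5/10 with replicates.
# Writes the count table, ground truth, heterozygous-SNP panel and
# known-polymorphism blacklist under results/.

library(poolsnv)

cfg <- default_run_config(seed = 1L)
study <- simulate_study(cfg)

dir.create("results", showWarnings = FALSE)
write_count_table(study$counts, "results/counts.tsv")
write.table(study$truth, "results/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(study$panel_sites[c("chrom", "pos")], "results/panel.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$blacklist, "results/blacklist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("experiments simulated: ", nrow(study$experiments))
message("count rows: ", nrow(study$counts))
tab <- table(study$truth$label)
message("truth labels: ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "))
message("mean depth by experiment:")
agg <- aggregate(depth ~ experiment_id, study$counts, mean)
print(agg, row.names = FALSE)
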