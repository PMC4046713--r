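#!/usr/bin/env Rscript
# De novo calling of novel single-sample variants in every pool: expected
# allele fraction 0.5 / N, window [half, twice] that value, blacklist and
# cross-experiment filters, then replicate intersection for
# high-confidence calls.

library(poolsnv)

counts <- read_count_table("results/counts.tsv")
blacklist <- read_site_list("results/blacklist.tsv", "tsv")
cfg <- denovo_config(blacklist = blacklist)

pools <- list(c("ALL1_pool2", 2), c("ALL2_pool5", 5), c("ALL1_pool10", 10))
all_calls <- list()
for (p in pools) {
  id <- p[[1]]
  n <- as.integer(p[[2]])
  rep_id <- paste0(id, "_rep")
  scan <- function(eid) {
    calls <- denovo_scan(counts[counts$experiment_id == eid, ], n, cfg,
                         other_counts = counts,
                         exclude_experiments = c(id, rep_id), pool_id = eid)
    att <- attr(calls, "attrition")
    message(sprintf("  %-16s %s", eid,
                    paste(names(att), att, sep = "=", collapse = " ")))
    calls
  }
  message(id, " filter attrition:")
  calls <- replicate_intersect(scan(id), scan(rep_id))
  n_hc <- length(unique(calls$pos[calls$high_confidence]))
  message(sprintf("%s: %d high-confidence novel SNVs, %d replicate-discordant",
                  id, n_hc, sum(!calls$high_confidence)))
  all_calls[[id]] <- calls
}
calls <- do.call(rbind, c(all_calls, list(make.row.names = FALSE)))
write.table(calls, "results/denovo_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("total high-confidence novel variants: ",
        nrow(unique(calls[calls$high_confidence,
                          c("chrom", "pos", "ref", "alt")])))
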