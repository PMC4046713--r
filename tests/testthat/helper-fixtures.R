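# Fixture builders shared across the suite.  All fixtures are constructed
# in code; nothing binary is stored.

make_counts <- function(pos, ref_count, alt_count, other_count = 0,
                        chrom = "chr1", ref = "A", alt = "T",
                        experiment_id = "e1", material = "gDNA",
                        kind = "tumor", pool_size = 1L) {
  n <- length(pos)
  data.frame(
    experiment_id = rep_len(experiment_id, n),
    material = rep_len(material, n),
    kind = rep_len(kind, n),
    pool_size = rep_len(as.integer(pool_size), n),
    chrom = rep_len(chrom, n),
    pos = pos,
    ref = rep_len(ref, n),
    alt = rep_len(alt, n),
    ref_count = rep_len(ref_count, n),
    alt_count = rep_len(alt_count, n),
    other_count = rep_len(other_count, n),
    stringsAsFactors = FALSE)
}

# minimal hand-written VCF with two SNV records and one indel record
write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tG\t50\tPASS\t.",
    "chr1\t200\trs2\tC\tT\t50\tPASS\t.",
    "chr1\t300\trs3\tC\tCAT\t50\tPASS\t."
  ), path)
  path
}

# a default full-study pipeline run, computed once and reused
get_default_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(default_run_config(seed = 42L))
    }
    cache
  }
})

# brute-force mean-absolute-difference Gini, the independent oracle
gini_brute_force <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}
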