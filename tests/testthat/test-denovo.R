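# helper: a one-row pool count table with a given AF at given depth
pool_row <- function(af, depth, pos = 100, n = 5, ...) {
  alt <- round(af * depth)
  make_counts(pos, depth - alt, alt, kind = "pool", pool_size = n,
              experiment_id = "pool5", ...)
}

test_that("the filter cascade calls and rejects hand-worked cases", {
  cfg <- denovo_config()
  # N=5: expected AF 0.1, window [0.05, 0.2], min total depth 150
  calls <- denovo_scan(pool_row(0.12, 200), 5, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$observed_af, 0.12)
  expect_equal(calls$expected_af, 0.1)

  # above twice the expected value: putatively multi-sample/germline
  expect_equal(nrow(denovo_scan(pool_row(0.30, 200), 5, cfg)), 0)
  # below half the expected value
  expect_equal(nrow(denovo_scan(pool_row(0.04, 200), 5, cfg)), 0)
  # window boundaries are inclusive on both ends
  expect_equal(nrow(denovo_scan(pool_row(0.05, 200), 5, cfg)), 1)
  expect_equal(nrow(denovo_scan(pool_row(0.20, 200), 5, cfg)), 1)
  # insufficient pooled depth (< 30 reads per pooled sample)
  expect_equal(nrow(denovo_scan(pool_row(0.12, 140), 5, cfg)), 0)
  # blacklisted position
  cfg_bl <- denovo_config(blacklist = data.frame(chrom = "chr1", pos = 100))
  expect_equal(nrow(denovo_scan(pool_row(0.12, 200), 5, cfg_bl)), 0)
  # de novo calling is defined for pools only
  expect_error(denovo_scan(pool_row(0.12, 200), 1, cfg), "configuration error")
})

test_that("the cross-experiment filter respects depth and replicate exemptions", {
  cfg <- denovo_config()
  pool <- pool_row(0.12, 200)
  other_hit <- make_counts(100, 98, 2, experiment_id = "unrelated")  # AF 0.02
  # present at 2% in another experiment: filtered
  expect_equal(nrow(denovo_scan(pool, 5, cfg, other_counts = other_hit)), 0)
  # the replicate experiment is exempt from the cross filter
  expect_equal(nrow(denovo_scan(pool, 5, cfg, other_counts = other_hit,
                                exclude_experiments = "unrelated")), 1)
  # shallow other experiments are not evidence
  shallow <- make_counts(100, 19, 1, experiment_id = "shallow")  # depth 20
  expect_equal(nrow(denovo_scan(pool, 5, cfg, other_counts = shallow)), 1)
  # at or below 1% elsewhere is tolerated
  low <- make_counts(100, 99, 1, experiment_id = "low")  # AF 0.01 exactly
  expect_equal(nrow(denovo_scan(pool, 5, cfg, other_counts = low)), 1)
})

test_that("every emitted call satisfies every filter predicate post hoc", {
  set.seed(91)
  n_sites <- 500
  depth <- rnbinom(n_sites, mu = 400, size = 8)
  af <- sample(c(0, 0.02, 0.08, 0.1, 0.25, 0.5), n_sites, replace = TRUE)
  alt <- rbinom(n_sites, depth, af)
  pool <- make_counts(seq_len(n_sites), depth - alt, alt,
                      kind = "pool", pool_size = 5)
  bl <- data.frame(chrom = "chr1", pos = sample(n_sites, 50))
  cfg <- denovo_config(blacklist = bl)
  calls <- denovo_scan(pool, 5, cfg, pool_id = "p")
  expect_true(all(calls$depth >= 150))
  expect_true(all(calls$observed_af >= 0.05 & calls$observed_af <= 0.2))
  expect_false(any(calls$pos %in% bl$pos))
  attrition <- attr(calls, "attrition")
  expect_true(all(diff(attrition) <= 0))
  expect_equal(unname(attrition[["cross_experiment"]]), nrow(calls))
})

test_that("replicate intersection separates high- and low-confidence calls", {
  a <- denovo_scan(pool_row(0.12, 200, pos = c(100, 200)), 5, denovo_config(),
                   pool_id = "p")
  b <- denovo_scan(pool_row(0.12, 200, pos = c(100, 300)), 5, denovo_config(),
                   pool_id = "p_rep")
  both <- replicate_intersect(a, b)
  expect_equal(nrow(both), 3)
  expect_equal(both$high_confidence[both$pos == 100], TRUE)
  expect_equal(sort(both$pos[!both$high_confidence]), c(200, 300))
  expect_equal(both$replicates[both$pos == 200], "p")
  expect_equal(both$replicates[both$pos == 300], "p_rep")

  all_conc <- replicate_intersect(a, a)
  expect_true(all(all_conc$high_confidence))
  empty <- replicate_intersect(a[0, ], a[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("planted single-sample variants are recovered with replicate concordance", {
  cfg <- cohort_config(seq_error = 0.001, seed = 101)
  planted <- data.frame(
    sample_id = "P1", chrom = "chr1", pos = seq(10, 60, by = 10),
    ref = "A", alt = "T", label = "somatic",
    true_af_tumor = 0.45, true_af_normal = 0,
    panel = FALSE, anchor = FALSE, stringsAsFactors = FALSE)
  # germline-like variants shared by two members (known polymorphisms)
  pair <- planted[1:3, ]
  pair$pos <- 1000 + pair$pos
  pair$label <- "germline"; pair$true_af_tumor <- 0.5; pair$true_af_normal <- 0.5
  pair <- rbind(transform(pair, sample_id = "M1"),
                transform(pair, sample_id = "M2"))
  truth <- rbind(planted, pair,
                 data.frame(sample_id = paste0("M", 3:4), chrom = "chr1",
                            pos = 5000 + 1:2, ref = "A", alt = "T",
                            label = "somatic", true_af_tumor = 0.05,
                            true_af_normal = 0, panel = FALSE, anchor = FALSE))
  background <- data.frame(chrom = "chr1", pos = 1e5 + 50 * (1:500),
                           ref = "G", alt = "C")
  pool <- pool_spec(c("P1", paste0("M", 1:4)))
  model <- depth_model(1500, 0.05)
  scan_rep <- function(seed, id) {
    counts <- simulate_experiment(truth, pool, model, cfg, id = id,
                                  background_sites = background,
                                  weight_concentration = NULL,
                                  seed = seed)$counts
    denovo_scan(counts, 5,
                denovo_config(blacklist = pair[c("chrom", "pos")]),
                pool_id = id)
  }
  calls <- replicate_intersect(scan_rep(111, "pool5"),
                               scan_rep(112, "pool5_rep"))
  hc <- calls[calls$high_confidence, ]
  expect_gte(sum(hc$pos %in% planted$pos), 5)
  expect_equal(sum(calls$pos %in% pair$pos), 0)
})
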