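test_that("cohort generation honors counts, privacy and determinism", {
  cfg <- cohort_config(n_somatic = 227, n_germline = 19, seed = 11)
  truth <- generate_cohort(cfg, c("S1", "S2"))
  s1 <- truth[truth$sample_id == "S1", ]
  expect_equal(sum(s1$label == "somatic"), 227)
  expect_equal(sum(s1$label == "germline"), 19)
  # somatic sites are private to one sample
  som <- truth[truth$label == "somatic", ]
  expect_false(any(duplicated(som[c("chrom", "pos")])))
  # germline panel is shared
  expect_equal(sum(truth$panel), 2 * 19)
  # truth label invariants
  expect_true(all(som$true_af_normal == 0))
  ger <- truth[truth$label == "germline", ]
  expect_true(all(ger$true_af_normal == 0.5))
  # deterministic given seed
  expect_identical(truth, generate_cohort(cfg, c("S1", "S2")))
})

test_that("subclonal mixture recovers its closed-form mean allele fraction", {
  cfg <- cohort_config(n_somatic = 2000, n_germline = 0,
                       subclone_af_means = c(0.2, 0.45),
                       subclone_weights = c(0.5, 0.5), seed = 3)
  truth <- generate_cohort(cfg)
  afs <- truth$true_af_tumor[truth$label == "somatic"]
  mixture_mean <- 0.5 * 0.2 + 0.5 * 0.45
  mixture_sd <- sqrt(0.5 * (0.2 - mixture_mean)^2 +
                       0.5 * (0.45 - mixture_mean)^2 + 0.04^2)
  expect_lt(abs(mean(afs) - mixture_mean), 3 * mixture_sd / sqrt(2000))
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(subclone_weights = c(0.5, 0.6)), "1")
  expect_error(cohort_config(seq_error = 0.2))
  expect_error(cohort_config(n_anchor = 10, n_somatic = 5),
               "configuration error")
})

test_that("weighted pooled allele fractions are mixing-weight averages", {
  expect_equal(true_pool_af(pool_spec(c("a", "b")), c(0.4, 0)), 0.2)
  # the lowest detectable individual fraction dilutes to 0.1 / N
  expect_equal(true_pool_af(pool_spec(letters[1:10]), c(0.1, rep(0, 9))),
               0.01)
  expect_equal(true_pool_af(pool_spec(letters[1:3], c(0.2, 0.3, 0.5)),
                            c(0, 0, 0)), 0)
  expect_error(true_pool_af(pool_spec(c("a", "b")), 0.4), "member")
  expect_error(pool_spec(c("a", "b"), c(0.7, 0.2)))
})

test_that("depth simulation is deterministic, dispersed by material, and has a degenerate limit", {
  expect_equal(simulate_depths(depth_model(850.2, 0), 5),
               rep(850, 5))
  g <- simulate_depths(depth_model_preset("gDNA"), 1e4, seed = 5)
  expect_identical(g, simulate_depths(depth_model_preset("gDNA"), 1e4, seed = 5))
  w <- simulate_depths(depth_model_preset("wgaDNA"), 1e4, seed = 5)
  expect_gt(gini_index(w), gini_index(g))
  expect_true(all(g >= 0) && all(g == round(g)))
})

test_that("site-count simulation conserves depth and has exact edge cases", {
  cnt <- simulate_site_counts(1, 500, seq_error = 0, seed = 1)
  expect_equal(cnt$alt_count, 500)
  cnt0 <- simulate_site_counts(0, 500, seq_error = 0, seed = 1)
  expect_equal(cnt0$alt_count, 0)
  # conservation across random mixtures
  af <- runif(500)
  dp <- sample(0:2000, 500, replace = TRUE)
  cnt <- simulate_site_counts(af, dp, seq_error = 0.01, seed = 2)
  expect_equal(cnt$ref_count + cnt$alt_count + cnt$other_count, cnt$depth)
  expect_true(all(cnt$ref_count >= 0 & cnt$other_count >= 0))
})

test_that("observed fractions are unbiased and concentrate with depth", {
  # binomial-tail scale at depth 10,000
  cnt <- simulate_site_counts(0.5, 1e4, seq_error = 0, seed = 7)
  expect_lt(abs(cnt$alt_count / cnt$depth - 0.5), 3 * sqrt(0.25 / 1e4))
  # mean recovery over 10,000 sites
  cnt <- simulate_site_counts(rep(0.3, 1e4), 500, seq_error = 0, seed = 8)
  se <- sqrt(0.3 * 0.7 / 500 / 1e4)
  expect_lt(abs(mean(cnt$alt_count / cnt$depth) - 0.3), 3 * se)
})

test_that("empirical pooled fractions converge to the weighted truth", {
  pool <- pool_spec(c("a", "b"), c(0.3, 0.7))
  target <- true_pool_af(pool, c(0.4, 0.1))
  cnt <- simulate_site_counts(target, 1e5, seq_error = 0, seed = 9)
  expect_lt(abs(cnt$alt_count / cnt$depth - target), 0.005)
})

test_that("simulated experiments compose truth, mixing and noise", {
  cfg <- cohort_config(n_somatic = 50, n_germline = 0, seq_error = 0, seed = 4)
  truth <- generate_cohort(cfg, c("S1", "S2"))
  sim <- simulate_experiment(truth, pool_spec("S1"),
                             depth_model(2000, 0), cfg,
                             id = "S1_gDNA", kind = "tumor", seed = 21)
  tr <- truth[truth$sample_id == "S1", ]
  m <- merge(sim$counts, tr, by = c("chrom", "pos", "ref", "alt"))
  af <- m$alt_count / (m$ref_count + m$alt_count + m$other_count)
  # single-sample pool reproduces the sample's truth up to binomial noise
  expect_lt(max(abs(af - m$true_af_tumor)), 4 * sqrt(0.25 / 2000))
  expect_equal(unique(sim$counts$pool_size), 1)

  # ten-sample equal-weight pool dilutes a private 0.45 variant to 0.045
  truth10 <- generate_cohort(cohort_config(n_somatic = 1, n_germline = 0,
                                           subclone_af_means = 0.45,
                                           subclone_weights = 1,
                                           subclone_af_sd = 0, seed = 5),
                             sprintf("P%02d", 1:10))
  sim10 <- simulate_experiment(truth10, pool_spec(sprintf("P%02d", 1:10)),
                               depth_model(1000, 0), cfg, id = "pool10",
                               weight_concentration = NULL, seed = 22)
  # each sample carries one private variant, so every site reads 0.45 / 10
  expect_equal(unique(round(sim10$true_af, 6)), 0.045)

  # replicates: same truth, independent counts
  rep_a <- simulate_experiment(truth, pool_spec(c("S1", "S2")),
                               depth_model(1000, 0.1), cfg, id = "a", seed = 31)
  rep_b <- simulate_experiment(truth, pool_spec(c("S1", "S2")),
                               depth_model(1000, 0.1), cfg, id = "b",
                               replicate_of = "a", seed = 32)
  expect_false(identical(rep_a$counts$alt_count, rep_b$counts$alt_count))
  expect_equal(rep_a$counts$pos, rep_b$counts$pos)
  expect_equal(sum(rep_a$weights), 1)

  expect_error(simulate_experiment(truth, pool_spec("S3"),
                                   depth_model(1000, 0), cfg, id = "x"),
               "absent from truth")
})
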