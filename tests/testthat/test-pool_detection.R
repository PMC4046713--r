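test_that("expected pooled allele fractions divide by pool size", {
  expect_equal(expected_pool_af(0.4, 10), 0.04)
  expect_equal(expected_pool_af(0.45, 2), 0.225)
  # lowest validated individual fraction 0.1 in a 10-pool
  expect_equal(expected_pool_af(0.1, 10), 0.01)
  expect_error(expected_pool_af(0.4, 0), ">= 1")
})

test_that("pool detection threshold boundary is inclusive", {
  thr10 <- detection_threshold(0.05, 10)
  expect_equal(thr10$value, 0.005)
  expect_true(detect_known(make_counts(1, 995, 5), thr10))      # 0.005 exactly
  expect_false(detect_known(make_counts(1, 9951, 49), thr10))   # 0.0049
  expect_true(detect_known(make_counts(1, 975, 25),
                           detection_threshold(0.05, 2)))       # 0.025
  expect_true(is.na(detect_known(make_counts(1, 0, 0), thr10)))
})

test_that("detection is monotone in allele fraction and anti-monotone in pool size", {
  afs <- seq(0, 0.02, by = 0.001)
  det <- detect_known(afs, detection_threshold(0.05, 10))
  expect_true(all(diff(det) >= 0))
  for (af in c(0.004, 0.01, 0.03)) {
    d <- vapply(1:10, function(n) detect_known(af, detection_threshold(0.05, n)),
                logical(1))
    expect_true(all(diff(d) >= 0))  # easier to detect in larger pools
  }
})

test_that("confusion matrices tally a hand-worked six-site pool", {
  pool <- make_counts(pos = 1:6,
                      alt_count = c(20, 4, 10, 0, 6, 0),
                      ref_count = c(980, 996, 990, 1000, 994, 1000))
  positives <- data.frame(chrom = "chr1", pos = 1:3)
  negatives <- data.frame(chrom = "chr1", pos = 4:6)
  cm <- pool_confusion_matrix(pool, positives, negatives,
                              detection_threshold(0.05, 10))
  expect_equal(cm$tp, 2)
  expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 2)
  expect_error(
    pool_confusion_matrix(pool, positives, data.frame(chrom = "chr1", pos = 3),
                          detection_threshold(0.05, 10)),
    "overlap")
  cm0 <- pool_confusion_matrix(pool, positives,
                               data.frame(chrom = character(0), pos = numeric(0)),
                               detection_threshold(0.05, 10))
  expect_equal(cm0$tn + cm0$fp, 0)
})

test_that("class totals are invariant to the threshold; only the split moves", {
  set.seed(61)
  pool <- make_counts(pos = 1:200, ref_count = 1000,
                      alt_count = rbinom(200, 1000, 0.01))
  positives <- data.frame(chrom = "chr1", pos = 1:120)
  negatives <- data.frame(chrom = "chr1", pos = 121:200)
  for (num in c(0.01, 0.05, 0.2, 0.6)) {
    cm <- pool_confusion_matrix(pool, positives, negatives,
                                detection_threshold(num, 10))
    expect_equal(cm$tp + cm$fn, 120)
    expect_equal(cm$tn + cm$fp, 80)
  }
})

test_that("zero-depth sites are excluded by default but countable as misses", {
  pool <- make_counts(pos = 1:3, ref_count = c(100, 0, 100),
                      alt_count = c(10, 0, 0))
  positives <- data.frame(chrom = "chr1", pos = 1:2)
  negatives <- data.frame(chrom = "chr1", pos = 3)
  thr <- detection_threshold(0.05, 2)
  cm <- pool_confusion_matrix(pool, positives, negatives, thr)
  expect_equal(c(cm$tp, cm$fn, cm$excluded_pos), c(1, 0, 1))
  cm2 <- pool_confusion_matrix(pool, positives, negatives, thr,
                               exclude_undetermined = FALSE)
  expect_equal(c(cm2$tp, cm2$fn, cm2$excluded_pos), c(1, 1, 0))
})

test_that("false discovery rate is FP / (TP + FP), reported as a percentage", {
  expect_equal(false_discovery_rate(confusion_matrix(224, 304, 1, 3)),
               100 * 1 / 225)
  expect_equal(false_discovery_rate(confusion_matrix(224, 304, 1, 3),
                                    percent = FALSE), 1 / 225)
  expect_error(false_discovery_rate(confusion_matrix(0, 10, 0, 5)),
               "undefined")
})

test_that("median ratio handles trivial, scaled and degenerate inputs", {
  expect_equal(median_ratio(c(0.1, 0.2), c(0.1, 0.2)), 1)
  x <- c(0.05, 0.1, 0.3)
  expect_equal(median_ratio(1.2 * x, x), 1.2)
  expect_equal(median_ratio(c(0.1, 0.4, 0.9), c(0.1, 0.2, 0.3)), 2)
  expect_warning(mr <- median_ratio(c(0.1, 0.2), c(0.1, 0)), "excluded")
  expect_equal(mr, 1)
  expect_error(suppressWarnings(median_ratio(0.1, 0)), "no sites")
})

test_that("allele-fraction rescaling divides by the median ratio and caps at 1", {
  expect_equal(scale_allele_fractions(c(0.1, 0.5), 1), c(0.1, 0.5))
  expect_equal(scale_allele_fractions(0.24, 1.2), 0.2)
  expect_equal(scale_allele_fractions(0.9, 0.5), 1)
  expect_error(scale_allele_fractions(0.1, 0), "positive")
})

test_that("a skewed pool's median ratio is recovered and rescaling is benign", {
  # focal sample over-represented 1.2x (weight 0.24 in a 5-pool)
  cfg <- cohort_config(n_somatic = 250, n_germline = 0, seq_error = 0.001,
                       seed = 71)
  others <- cohort_config(n_somatic = 1, n_germline = 0, seed = 72)
  truth <- rbind(generate_cohort(cfg, "F"),
                 generate_cohort(others, paste0("M", 1:4), pos_offset = 1e6))
  pool <- pool_spec(c("F", paste0("M", 1:4)))
  model <- depth_model(1500, 0.02)
  ind <- simulate_experiment(truth, pool_spec("F"), model, cfg,
                             id = "F_gDNA", seed = 81)$counts
  pl <- simulate_experiment(truth, pool, model, cfg, id = "pool5",
                            stock_weights = c(0.24, rep(0.19, 4)),
                            weight_concentration = NULL, seed = 82)$counts
  focal_sites <- truth[truth$sample_id == "F" & truth$label == "somatic", ]
  ind <- with_allele_fractions(merge(ind, focal_sites[c("chrom", "pos")]))
  pl <- with_allele_fractions(merge(pl, focal_sites[c("chrom", "pos")]))
  m <- merge(ind[c("chrom", "pos", "af", "depth")],
             pl[c("chrom", "pos", "af", "depth")],
             by = c("chrom", "pos"), suffixes = c("_ind", "_pool"))
  m <- m[m$depth_ind >= 1000 & m$depth_pool >= 1000, ]
  expect_gte(nrow(m), 200)
  mr <- median_ratio(m$af_pool, expected_pool_af(m$af_ind, 5))
  expect_gt(mr, 1.1)
  expect_lt(mr, 1.3)
  # rescaling by the median ratio changes at most one detection call
  thr <- detection_threshold(0.05, 5)
  before <- detect_known(m$af_pool, thr)
  after <- detect_known(scale_allele_fractions(m$af_pool, mr), thr)
  expect_lte(sum(before != after), 1)
})
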