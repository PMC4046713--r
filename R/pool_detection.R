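# Detection of known somatic SNVs in non-indexed pools: detection rule,
# confusion matrices, false discovery rate, median-ratio pool skew, and
# allele-fraction rescaling.

#' Detection threshold for known somatic SNVs in a pool
#'
#' A validated somatic SNV present in a single pool member is considered
#' detected when the pooled allele fraction is at least `numerator / N`
#' (inclusive).  With `numerator = 0.05` this is half the lowest expected
#' pooled allele fraction of a validated somatic SNV (individual allele
#' fraction cutoff 0.1 divided by pool size), allowing for mixing
#' inaccuracy and sampling variation.
#'
#' @param numerator threshold numerator in (0, 1); default 0.05.
#' @param pool_size pool size N >= 1.
#' @return list of class `detection_threshold` with the derived `value =
#'   numerator / pool_size`.
#' @export
detection_threshold <- function(numerator = 0.05, pool_size = 1) {
  stopifnot(numerator > 0, numerator < 1, pool_size >= 1)
  structure(list(numerator = numerator, pool_size = pool_size,
                 value = numerator / pool_size),
            class = "detection_threshold")
}

#' Expected pooled allele fraction of a single-sample variant
#'
#' @param individual_af allele fraction observed in the individual sample.
#' @param n pool size (>= 1).
#' @return `individual_af / n`.
#' @export
expected_pool_af <- function(individual_af, n) {
  if (any(n < 1)) stop("pool size must be >= 1")
  individual_af / n
}

#' Detect known somatic SNVs in pooled counts
#'
#' @param pool_counts count rows for the pool (needs `ref_count`,
#'   `alt_count`, `other_count`); alternatively a numeric vector of
#'   observed allele fractions.
#' @param threshold a [detection_threshold()].
#' @return logical vector: `TRUE` where the allele fraction is `>=
#'   threshold$value`; `NA` (undetermined) at zero-depth rows.
#' @export
detect_known <- function(pool_counts, threshold) {
  stopifnot(inherits(threshold, "detection_threshold"))
  if (is.numeric(pool_counts)) {
    af <- pool_counts
  } else {
    depth <- pool_counts$ref_count + pool_counts$alt_count +
      pool_counts$other_count
    af <- ifelse(depth > 0, pool_counts$alt_count / pmax(depth, 1), NA_real_)
  }
  af >= threshold$value
}

#' Confusion matrix for pool detection of known somatic SNVs
#'
#' Known somatic SNVs of the in-pool reference sample are the positive
#' sites (detected = TP, missed = FN); known somatic SNVs of a sample
#' *not* in the pool are the negatives (detected = FP, undetected = TN) —
#' somatic SNVs are private, so one patient's SNVs are absent from pools
#' containing only the other patient.  Sites absent from the pool readout
#' or at zero depth are excluded from the tallies and counted separately
#' (capture failure, not detection failure); set `exclude_undetermined =
#' FALSE` to count them as FN/TN instead.
#'
#' @param pool_counts count-table rows of the pool experiment.
#' @param positives,negatives disjoint site data frames (`chrom`, `pos`,
#'   and optionally `ref`, `alt`).
#' @param threshold a [detection_threshold()].
#' @param exclude_undetermined drop zero-depth/missing sites from the
#'   tallies (default `TRUE`).
#' @return list of class `confusion_matrix` with `tp`, `tn`, `fp`, `fn`,
#'   `excluded_pos`, `excluded_neg`, and `classes` (per-site table with
#'   class in TP/FN/FP/TN/excluded).
#' @export
pool_confusion_matrix <- function(pool_counts, positives, negatives, threshold,
                                  exclude_undetermined = TRUE) {
  stopifnot(inherits(threshold, "detection_threshold"))
  pos_keys <- site_key(positives$chrom, positives$pos)
  neg_keys <- site_key(negatives$chrom, negatives$pos)
  if (length(intersect(pos_keys, neg_keys))) {
    stop("positive and negative site sets overlap")
  }
  pool_keys <- site_key(pool_counts$chrom, pool_counts$pos)
  depth <- pool_counts$ref_count + pool_counts$alt_count +
    pool_counts$other_count
  af <- ifelse(depth > 0, pool_counts$alt_count / pmax(depth, 1), NA_real_)

  eval_sites <- function(keys, sites, positive) {
    idx <- match(keys, pool_keys)
    observed_af <- af[idx]
    det <- !is.na(observed_af) & observed_af >= threshold$value
    undetermined <- is.na(idx) | (!is.na(idx) & depth[idx] == 0)
    class <- if (positive) ifelse(det, "TP", "FN") else ifelse(det, "FP", "TN")
    if (exclude_undetermined) class[undetermined] <- "excluded"
    data.frame(sites[c("chrom", "pos")], observed_af = observed_af,
               detected = det, class = class, stringsAsFactors = FALSE)
  }
  pos_tab <- eval_sites(pos_keys, positives, TRUE)
  neg_tab <- eval_sites(neg_keys, negatives, FALSE)
  classes <- rbind(pos_tab, neg_tab)
  tally <- function(cl) sum(classes$class == cl)
  structure(list(
    tp = tally("TP"), tn = tally("TN"), fp = tally("FP"), fn = tally("FN"),
    excluded_pos = sum(pos_tab$class == "excluded"),
    excluded_neg = sum(neg_tab$class == "excluded"),
    classes = classes
  ), class = "confusion_matrix")
}

#' Construct a confusion matrix from tallies
#'
#' @param tp,tn,fp,fn non-negative integer tallies.
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 excluded_pos = 0L, excluded_neg = 0L),
            class = "confusion_matrix")
}

#' False discovery rate of pool detection
#'
#' `FDR = FP / (TP + FP)`, reported as a percentage by default (the raw
#' fraction via `percent = FALSE`).
#'
#' @param cm a `confusion_matrix`.
#' @param percent report `100 * fp / (tp + fp)` (default) instead of the
#'   raw fraction.
#' @return the false discovery rate; error when `tp + fp = 0` (no
#'   detections, FDR undefined).
#' @export
false_discovery_rate <- function(cm, percent = TRUE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fp == 0) stop("FDR undefined: no positive calls (tp + fp = 0)")
  frac <- cm$fp / (cm$tp + cm$fp)
  if (percent) 100 * frac else frac
}

#' Median ratio between observed and expected allele fractions
#'
#' The median over sites of `observed / expected`.  Values above 1 mean
#' the focal sample is over-represented in the pool relative to its
#' nominal mixing proportion.  Sites with expected allele fraction 0 are
#' excluded with a warning (the ratio is undefined there).
#'
#' @param observed,expected equal-length numeric vectors.
#' @return the median ratio (MR).
#' @export
median_ratio <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) > 0)
  zero <- expected == 0
  if (any(zero)) {
    warning(sum(zero), " site(s) with zero expected allele fraction excluded")
    observed <- observed[!zero]
    expected <- expected[!zero]
  }
  if (!length(observed)) stop("no sites with positive expected allele fraction")
  median(observed / expected)
}

#' Rescale observed allele fractions by a median ratio
#'
#' Divides observed pooled allele fractions by the median ratio to correct
#' for over- or under-representation of the focal sample in the pool;
#' rescaled values are capped at 1.
#'
#' @param afs numeric allele fractions.
#' @param mr positive median ratio.
#' @return `pmin(afs / mr, 1)`.
#' @export
scale_allele_fractions <- function(afs, mr) {
  if (!is.numeric(mr) || length(mr) != 1 || mr <= 0) {
    stop("median ratio must be a single positive number")
  }
  pmin(afs / mr, 1)
}
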