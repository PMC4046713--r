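# Replicate/material concordance and coverage-evenness statistics.

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 2, non-constant).
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  cor(x, y, method = "pearson")
}

#' Root mean square error between paired vectors
#'
#' @param x,y equal-length non-empty numeric vectors.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("rmse: length mismatch")
  stopifnot(length(x) > 0)
  sqrt(mean((x - y)^2))
}

#' Coefficient of variation of per-site depths
#'
#' Standard deviation divided by the mean; the population standard
#' deviation (denominator n) by default, with the sample version
#' (denominator n - 1) as an option.  Scale-invariant.
#'
#' @param depths non-empty numeric vector with positive mean.
#' @param sample_sd use the n-1 denominator (default `FALSE`).
#' @return the coefficient of variation (>= 0).
#' @export
coefficient_of_variation <- function(depths, sample_sd = FALSE) {
  stopifnot(length(depths) > 0)
  m <- mean(depths)
  if (m <= 0) stop("coefficient of variation undefined for non-positive mean")
  if (sample_sd) {
    if (length(depths) < 2) stop("sample SD needs at least two values")
    sd(depths) / m
  } else {
    sqrt(mean((depths - m)^2)) / m
  }
}

#' Gini index of per-site depths
#'
#' Coverage-evenness measure: 0 for perfectly even coverage, approaching 1
#' when coverage concentrates on few sites.  Uses the mean-absolute-
#' difference definition `G = sum_ij |x_i - x_j| / (2 n^2 mu)` (no
#' small-sample correction by default; `corrected = TRUE` multiplies by
#' `n / (n - 1)`).  Scale-invariant.
#'
#' @param depths non-empty vector of non-negative depths with positive sum.
#' @param corrected apply the `n / (n - 1)` small-sample factor.
#' @return the Gini index in `[0, 1]`.
#' @export
gini_index <- function(depths, corrected = FALSE) {
  n <- length(depths)
  stopifnot(n > 0, all(depths >= 0))
  if (sum(depths) == 0) stop("Gini index undefined for all-zero depths")
  if (n == 1) return(0)
  x <- sort(depths)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  g <- sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
  if (corrected) g <- g * n / (n - 1)
  g
}

#' Concordance report between two allele-fraction readouts
#'
#' @param x,y paired allele fractions (e.g. genomic DNA vs. whole-genome-
#'   amplified DNA from the same sample).
#' @return list with `pearson_r`, `rmse` and `n_sites`.
#' @export
concordance_report <- function(x, y) {
  list(pearson_r = pearson_correlation(x, y), rmse = rmse(x, y),
       n_sites = length(x))
}

#' Coverage-evenness report for one experiment
#'
#' @param depths per-site depths.
#' @inheritParams coefficient_of_variation
#' @return list with `cv`, `gini` and `n_sites`.
#' @export
evenness_report <- function(depths, sample_sd = FALSE) {
  list(cv = coefficient_of_variation(depths, sample_sd = sample_sd),
       gini = gini_index(depths), n_sites = length(depths))
}
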