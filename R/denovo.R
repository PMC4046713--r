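# De novo calling of novel single-sample variants in non-indexed pools:
# expected-allele-fraction window, known-polymorphism blacklist,
# cross-experiment filter, and replicate concordance.

#' Configuration of the de novo pool-calling cascade
#'
#' A novel variant present in a single (diploid, heterozygous) pool member
#' has expected pooled allele fraction `expected_numerator / N`.  A site is
#' called when all of the following hold: total pool depth at least
#' `per_sample_min_depth * N`; observed allele fraction within
#' `[window_low_factor, window_high_factor]` times the expected value
#' (both ends inclusive — variants with a fraction *less than* half or
#' *more than* twice the expected value are excluded); the site is not a
#' known polymorphism (blacklist); and the allele fraction does not exceed
#' `cross_experiment_max_af` in any other experiment with informative
#' depth at the site (the replicate pool is exempt).
#'
#' @param expected_numerator expected single-sample allele fraction
#'   (default 0.5, a heterozygous variant).
#' @param window_low_factor,window_high_factor inclusive window around the
#'   expected pooled allele fraction (defaults 0.5 and 2).
#' @param per_sample_min_depth minimum depth per pooled sample
#'   (default 30); reads are unindexed, so this is applied as a total pool
#'   depth of `per_sample_min_depth * N`.
#' @param cross_experiment_max_af maximum allele fraction tolerated in any
#'   other experiment (default 0.01, i.e. variants above 1% elsewhere are
#'   filtered as germline or recurrent artifacts).
#' @param min_cross_depth minimum depth for another experiment to count as
#'   informative at a site (default 30).
#' @param blacklist data frame of known-polymorphism sites (`chrom`,
#'   `pos`), e.g. from [read_site_list()]; matching is positional.
#' @return list of class `denovo_config`.
#' @export
denovo_config <- function(expected_numerator = 0.5,
                          window_low_factor = 0.5,
                          window_high_factor = 2,
                          per_sample_min_depth = 30,
                          cross_experiment_max_af = 0.01,
                          min_cross_depth = 30,
                          blacklist = NULL) {
  stopifnot(expected_numerator > 0, expected_numerator <= 1,
            window_low_factor > 0, window_low_factor < 1,
            window_high_factor > 1,
            per_sample_min_depth >= 0,
            cross_experiment_max_af >= 0, cross_experiment_max_af < 1,
            min_cross_depth >= 0)
  structure(list(expected_numerator = expected_numerator,
                 window_low_factor = window_low_factor,
                 window_high_factor = window_high_factor,
                 per_sample_min_depth = per_sample_min_depth,
                 cross_experiment_max_af = cross_experiment_max_af,
                 min_cross_depth = min_cross_depth,
                 blacklist = blacklist),
            class = "denovo_config")
}

#' Scan a pool for novel single-sample variants
#'
#' Applies the full filter cascade over all sites in the pool count table
#' (which should be restricted to the target region).  Calls are reported
#' per pool only: reads are unindexed, so no member attribution is
#' attempted.
#'
#' @param pool_counts count-table rows of one pool experiment, covering
#'   the target-region sites to scan (each row carries the alternate
#'   allele evaluated at that site).
#' @param n pool size (>= 2: de novo pool calling is defined for pools).
#' @param cfg a [denovo_config()].
#' @param other_counts count-table rows of the other experiments in the
#'   study, used for the cross-experiment filter (may be `NULL`).
#' @param exclude_experiments experiment ids exempt from the
#'   cross-experiment filter: the scanned pool itself and its replicate.
#' @param pool_id identifier recorded in the calls.
#' @return data frame of calls (chrom, pos, ref, alt, pool_id,
#'   observed_af, depth, expected_af, filters_passed, high_confidence =
#'   `FALSE` until replicate intersection), with attribute `attrition`
#'   giving the number of sites passing each filter.
#' @export
denovo_scan <- function(pool_counts, n, cfg = denovo_config(),
                        other_counts = NULL,
                        exclude_experiments = character(),
                        pool_id = "pool") {
  stopifnot(inherits(cfg, "denovo_config"))
  if (n < 2) stop("configuration error: de novo calling requires a pool (n >= 2)")
  depth <- pool_counts$ref_count + pool_counts$alt_count +
    pool_counts$other_count
  af <- ifelse(depth > 0, pool_counts$alt_count / pmax(depth, 1), NA_real_)
  expected <- cfg$expected_numerator / n
  lo <- cfg$window_low_factor * expected
  hi <- cfg$window_high_factor * expected

  pass_depth <- depth >= cfg$per_sample_min_depth * n
  pass_window <- !is.na(af) & af >= lo & af <= hi
  keys <- site_key(pool_counts$chrom, pool_counts$pos)
  pass_blacklist <- if (is.null(cfg$blacklist) || !nrow(cfg$blacklist)) {
    rep(TRUE, nrow(pool_counts))
  } else {
    !(keys %in% site_key(cfg$blacklist$chrom, cfg$blacklist$pos))
  }
  pass_cross <- rep(TRUE, nrow(pool_counts))
  if (!is.null(other_counts) && nrow(other_counts)) {
    oth <- other_counts[!(other_counts$experiment_id %in% exclude_experiments), ,
                        drop = FALSE]
    if (nrow(oth)) {
      o_depth <- oth$ref_count + oth$alt_count + oth$other_count
      informative <- o_depth >= cfg$min_cross_depth & o_depth > 0
      oth <- oth[informative, , drop = FALSE]
      if (nrow(oth)) {
        o_af <- oth$alt_count / (oth$ref_count + oth$alt_count + oth$other_count)
        o_keys <- site_key(oth$chrom, oth$pos)
        max_af <- tapply(o_af, o_keys, max)
        hit <- max_af[keys]
        pass_cross <- is.na(hit) | hit <= cfg$cross_experiment_max_af
      }
    }
  }

  called <- pass_depth & pass_window & pass_blacklist & pass_cross
  idx <- which(called)
  calls <- data.frame(
    chrom = pool_counts$chrom[idx], pos = pool_counts$pos[idx],
    ref = pool_counts$ref[idx], alt = pool_counts$alt[idx],
    pool_id = rep(pool_id, length(idx)),
    observed_af = af[idx],
    depth = depth[idx],
    expected_af = rep(expected, length(idx)),
    filters_passed = rep("depth;af_window;blacklist;cross_experiment",
                         length(idx)),
    high_confidence = rep(FALSE, length(idx)),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "attrition") <- c(
    sites = nrow(pool_counts),
    depth = sum(pass_depth),
    af_window = sum(pass_depth & pass_window),
    blacklist = sum(pass_depth & pass_window & pass_blacklist),
    cross_experiment = sum(called))
  calls
}

#' Intersect de novo calls from replicate pools
#'
#' A call is high-confidence when it appears (same position and alternate
#' allele) in both independently prepared replicates of a pool; calls seen
#' in only one replicate are retained as low-confidence with provenance.
#'
#' @param calls_a,calls_b call data frames from [denovo_scan()] on the two
#'   replicates of a pool of identical composition.
#' @return combined data frame with `high_confidence` set for concordant
#'   calls and a `replicates` column naming the replicate(s) each call was
#'   seen in.
#' @export
replicate_intersect <- function(calls_a, calls_b) {
  key <- function(df) variant_key(df$chrom, df$pos, df$ref, df$alt)
  ka <- key(calls_a)
  kb <- key(calls_b)
  both <- intersect(ka, kb)
  a <- calls_a
  a$replicates <- ifelse(ka %in% both,
                         paste(unique(c(calls_a$pool_id, calls_b$pool_id)),
                               collapse = ";"),
                         calls_a$pool_id)
  a$high_confidence <- ka %in% both
  b_only <- calls_b[!(kb %in% ka), , drop = FALSE]
  if (nrow(b_only)) {
    b_only$replicates <- b_only$pool_id
    b_only$high_confidence <- FALSE
  } else {
    b_only$replicates <- character(0)
  }
  out <- rbind(a, b_only)
  rownames(out) <- NULL
  out
}
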