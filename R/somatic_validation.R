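# Somatic vs. non-validated classification from paired tumor/normal
# allele fractions, and the heterozygous-SNP deviation statistic.

#' Thresholds for somatic classification
#'
#' A candidate SNV is classified somatic when its allele fraction is
#' `>= min_tumor_af` in the tumor sample and `< max_normal_af` in the
#' matched normal, with depth `>= min_depth` in both (boundaries inclusive
#' on the tumor allele fraction and depth, exclusive on the normal allele
#' fraction).
#'
#' @param min_tumor_af inclusive minimum tumor allele fraction (default 0.1).
#' @param max_normal_af exclusive maximum normal allele fraction
#'   (default 0.01).
#' @param min_depth inclusive minimum depth in both samples (default 30).
#' @return list of class `validation_thresholds`.
#' @export
validation_thresholds <- function(min_tumor_af = 0.1, max_normal_af = 0.01,
                                  min_depth = 30) {
  stopifnot(min_tumor_af > 0, min_tumor_af < 1,
            max_normal_af >= 0, max_normal_af < min_tumor_af,
            min_depth >= 1)
  structure(list(min_tumor_af = min_tumor_af, max_normal_af = max_normal_af,
                 min_depth = min_depth), class = "validation_thresholds")
}

#' Classify candidate SNVs as somatic or non-validated
#'
#' @param tumor,normal count rows for the same site(s) (data frames with
#'   `ref_count`, `alt_count`, `other_count`, and site columns if
#'   available); rows are paired positionally and sites are checked for
#'   identity when coordinates are present.
#' @param thresholds a [validation_thresholds()].
#' @return character vector with one of `"somatic"`, `"non_validated"`,
#'   `"insufficient_depth"` per pair.
#' @export
classify_somatic <- function(tumor, normal, thresholds = validation_thresholds()) {
  stopifnot(inherits(thresholds, "validation_thresholds"),
            nrow(tumor) == nrow(normal))
  if (all(c("chrom", "pos") %in% names(tumor)) &&
      all(c("chrom", "pos") %in% names(normal))) {
    if (!all(tumor$chrom == normal$chrom & tumor$pos == normal$pos)) {
      stop("tumor and normal records refer to different sites")
    }
  }
  t_depth <- tumor$ref_count + tumor$alt_count + tumor$other_count
  n_depth <- normal$ref_count + normal$alt_count + normal$other_count
  status <- rep("insufficient_depth", nrow(tumor))
  ok <- t_depth >= thresholds$min_depth & n_depth >= thresholds$min_depth
  t_af <- ifelse(t_depth > 0, tumor$alt_count / pmax(t_depth, 1), NA_real_)
  n_af <- ifelse(n_depth > 0, normal$alt_count / pmax(n_depth, 1), NA_real_)
  somatic <- ok & t_af >= thresholds$min_tumor_af & n_af < thresholds$max_normal_af
  status[ok] <- "non_validated"
  status[which(somatic)] <- "somatic"
  status
}

#' Validate a cohort of candidate SNVs against the matched normal
#'
#' Pairs tumor and normal count tables by site; candidates missing from
#' either table (capture dropout) are reported as `insufficient_depth`
#' rather than an error.
#'
#' @param tumor_counts,normal_counts count-table data frames for one
#'   tumor/normal pair (single experiment each).
#' @param thresholds a [validation_thresholds()].
#' @return list with `status_table` (chrom, pos, ref, alt, tumor_af,
#'   normal_af, tumor_depth, normal_depth, status) and `summary` (named
#'   counts per status).
#' @export
validate_cohort <- function(tumor_counts, normal_counts,
                            thresholds = validation_thresholds()) {
  site_cols <- c("chrom", "pos", "ref", "alt")
  empty_summary <- c(somatic = 0L, non_validated = 0L, insufficient_depth = 0L)
  if (!nrow(tumor_counts) && !nrow(normal_counts)) {
    return(list(status_table = data.frame(), summary = empty_summary))
  }
  sites <- unique(rbind(tumor_counts[site_cols], normal_counts[site_cols]))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  keys <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  align <- function(counts) {
    idx <- match(keys, variant_key(counts$chrom, counts$pos,
                                   counts$ref, counts$alt))
    out <- data.frame(ref_count = rep(0L, length(keys)), alt_count = 0L,
                      other_count = 0L)
    ok <- !is.na(idx)
    out[ok, ] <- counts[idx[ok], c("ref_count", "alt_count", "other_count")]
    out
  }
  tum <- align(tumor_counts)
  nor <- align(normal_counts)
  status <- classify_somatic(tum, nor, thresholds)
  t_depth <- tum$ref_count + tum$alt_count + tum$other_count
  n_depth <- nor$ref_count + nor$alt_count + nor$other_count
  tab <- data.frame(
    sites,
    tumor_af = ifelse(t_depth > 0, tum$alt_count / pmax(t_depth, 1), NA_real_),
    normal_af = ifelse(n_depth > 0, nor$alt_count / pmax(n_depth, 1), NA_real_),
    tumor_depth = t_depth, normal_depth = n_depth,
    status = status, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  summ <- empty_summary
  counted <- table(status)
  summ[names(counted)] <- as.integer(counted)
  list(status_table = tab, summary = summ)
}

#' Mean absolute deviation of heterozygous-SNP allele fractions from 0.5
#'
#' Heterozygous germline SNPs have expected allele fraction 0.5; the mean
#' absolute deviation from 0.5 measures the precision of allele fractions
#' in a dataset (deeper sequencing gives smaller deviation).
#'
#' @param afs non-empty numeric vector of allele fractions at known
#'   heterozygous SNPs.
#' @return mean of `|af - 0.5|`.
#' @export
het_snp_deviation <- function(afs) {
  if (length(afs) == 0) stop("no heterozygous-SNP allele fractions supplied")
  stopifnot(all(is.finite(afs)))
  mean(abs(afs - 0.5))
}
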