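# Count-table I/O and allele-fraction primitives.
#
# The pipeline contract starts at per-site read counts: one row per
# (experiment, site) with ref/alt/other read counts at a single-nucleotide
# variant site.  Coordinates are 1-based inclusive throughout; BED input is
# 0-based half-open and converted on load.  A row carries exactly one alt
# allele: two alternate alleles at one position are two rows.

DNA_BASES <- c("A", "C", "G", "T")

COUNT_TABLE_COLUMNS <- c(
  "experiment_id", "material", "kind", "pool_size",
  "chrom", "pos", "ref", "alt",
  "ref_count", "alt_count", "other_count"
)

# positional site key (used for blacklists) and allele-resolved key
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Validate variant-site fields
#'
#' Checks the invariants of a single-nucleotide variant site: positive
#' 1-based position, single uppercase A/C/G/T alleles, ref distinct from alt.
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending rows.
#' @export
validate_variant_sites <- function(df) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  bad <- which(
    !is.finite(df$pos) | df$pos < 1 | df$pos != round(df$pos) |
      !(df$ref %in% DNA_BASES) | !(df$alt %in% DNA_BASES) |
      df$ref == df$alt
  )
  if (length(bad)) {
    stop("invalid variant site(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  invisible(df)
}

validate_count_rows <- function(df) {
  cnt <- c("ref_count", "alt_count", "other_count")
  stopifnot(all(cnt %in% names(df)))
  for (col in cnt) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 |
                   df[[col]] != round(df[[col]]))
    if (length(bad)) {
      stop("negative or non-integer ", col, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
  }
  invisible(df)
}

#' Read a per-site read-count table
#'
#' Reads the tab-separated count-table dialect used throughout the pipeline:
#' a header line followed by one row per (experiment, site) with columns
#' `experiment_id`, `material`, `kind`, `pool_size`, `chrom`, `pos`, `ref`,
#' `alt`, `ref_count`, `alt_count`, `other_count`.  Lines starting with `#`
#' are comments.  Site and count invariants are validated on load.
#'
#' @param path path to a TSV file.
#' @return data frame of validated count rows with an additional `depth`
#'   column (`ref_count + alt_count + other_count`).
#' @seealso [write_count_table()], [allele_fraction()]
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = c(experiment_id = "character",
                              material = "character", kind = "character",
                              chrom = "character",
                              ref = "character", alt = "character",
                              pool_size = "integer", pos = "numeric",
                              ref_count = "numeric", alt_count = "numeric",
                              other_count = "numeric")),
    error = function(e) stop("malformed count table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(COUNT_TABLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("count table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[COUNT_TABLE_COLUMNS]
  if (nrow(df)) {
    validate_variant_sites(df)
    validate_count_rows(df)
    if (any(df$pool_size < 1)) stop("pool_size must be >= 1")
  }
  df$depth <- df$ref_count + df$alt_count + df$other_count
  df
}

#' Write a per-site read-count table
#'
#' @param counts data frame of count rows (the dialect of
#'   [read_count_table()]; a `depth` column, if present, is not written
#'   since it is derived).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(all(COUNT_TABLE_COLUMNS %in% names(counts)))
  write.table(counts[COUNT_TABLE_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele fraction at a site
#'
#' The fraction of reads supporting the alternate allele.  By default the
#' denominator is the total depth (`ref + alt + other`), with a
#' `ref_alt`-only denominator available; at realistic error rates the
#' difference is negligible relative to every decision threshold.
#'
#' @param ref_count,alt_count,other_count non-negative read counts
#'   (vectorized).
#' @param denominator `"total"` (default) or `"ref_alt"`.
#' @return numeric vector of fractions in `[0, 1]`.  A zero denominator is
#'   an error: an undefined fraction is distinct from a fraction of 0.
#' @export
allele_fraction <- function(ref_count, alt_count, other_count = 0,
                            denominator = c("total", "ref_alt")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                total   = ref_count + alt_count + other_count,
                ref_alt = ref_count + alt_count)
  if (any(den == 0)) {
    stop("allele fraction undefined at zero ", denominator, " depth")
  }
  alt_count / den
}

#' Append depth and allele-fraction columns to a count table
#'
#' @param counts count-table data frame.
#' @inheritParams allele_fraction
#' @return `counts` with `depth` and `af` columns; `af` is `NA` where the
#'   denominator is zero (those rows carry no allele-fraction information).
#' @export
with_allele_fractions <- function(counts, denominator = c("total", "ref_alt")) {
  denominator <- match.arg(denominator)
  counts$depth <- counts$ref_count + counts$alt_count + counts$other_count
  den <- if (denominator == "total") counts$depth else
    counts$ref_count + counts$alt_count
  counts$af <- ifelse(den > 0, counts$alt_count / pmax(den, 1), NA_real_)
  counts
}

#' Filter count rows by minimum depth
#'
#' @param counts count-table data frame.
#' @param min_depth inclusive minimum total depth (>= 0).
#' @return the rows with `ref_count + alt_count + other_count >= min_depth`.
#' @export
depth_filter <- function(counts, min_depth) {
  stopifnot(is.numeric(min_depth), length(min_depth) == 1, min_depth >= 0)
  depth <- counts$ref_count + counts$alt_count + counts$other_count
  counts[depth >= min_depth, , drop = FALSE]
}

#' Read a site list (blacklist) from TSV or VCF
#'
#' Loads a deduplicated set of single-nucleotide variant sites, e.g. a
#' known-polymorphism blacklist standing in for dbSNP.  The TSV form is two
#' columns (`chrom`, `pos`), with or without a header; the VCF form keeps
#' SNV records only — records with indel alleles are skipped with a
#' warning, and multi-allelic SNV records contribute one site per alternate
#' base.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return data frame with columns `chrom`, `pos` (and `ref`, `alt` for
#'   VCF input), deduplicated.
#' @export
read_site_list <- function(path, format = c("tsv", "vcf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown site-list format: ",
                                              format[1], call. = FALSE))
  if (!file.exists(path)) stop("site list not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("site-list TSV needs two columns (chrom, pos)")
    df <- df[, 1:2]
    names(df) <- c("chrom", "pos")
    # tolerate an optional header line
    if (is.na(suppressWarnings(as.numeric(df$pos[1]))) && nrow(df) > 0) {
      df <- df[-1, , drop = FALSE]
    }
    df$pos <- as.numeric(df$pos)
    df$chrom <- as.character(df$chrom)
    df <- unique(df)
    rownames(df) <- NULL
    return(df)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character()))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    snv <- nchar(ref) == 1 & nchar(alts) == 1 &
      ref %in% DNA_BASES & alts %in% DNA_BASES
    if (!any(snv)) {
      warning("skipping non-SNV VCF record at ", fix$CHROM[i], ":",
              fix$POS[i], call. = FALSE)
      return(NULL)
    }
    data.frame(chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
               ref = ref, alt = alts[snv], stringsAsFactors = FALSE)
  }))
  out <- unique(out)
  rownames(out) <- NULL
  validate_variant_sites(out)
  out
}

#' Read target regions from a BED3 file
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' inclusive convention used by count tables and site lists.
#'
#' @param path BED file path.
#' @return data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_target_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  data.frame(chrom = as.character(gr$seqnames),
             start = gr$start, end = gr$end,
             stringsAsFactors = FALSE)
}
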