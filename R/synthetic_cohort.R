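# Synthetic pooled-tumor cohort generator.
#
# Emulates the statistical structure of a deep targeted-sequencing study of
# leukemia samples: per-patient candidate SNV sites with subclonal
# allele-fraction clusters, shared heterozygous germline SNPs (with an
# optional loss-of-heterozygosity subset), whole-genome-amplification-style
# coverage overdispersion, and non-indexed pools with imperfect mixing.
# It generates *counts*, not reads: capture-probe layout and read-level
# artifacts are out of scope.

#' Configuration for a synthetic tumor cohort
#'
#' @param n_somatic somatic SNVs per sample (private to that sample).
#' @param n_germline heterozygous germline panel SNPs shared across
#'   samples (expected allele fraction 0.5 in tumor and normal).
#' @param n_germline_escapee per-sample germline variants that pose as
#'   somatic candidates (allele fraction ~0.5 in both tumor and normal;
#'   the "diagonal" pattern of candidate validation plots).
#' @param n_null_candidates per-sample candidate sites carrying no true
#'   variant (false positives of upstream calling; allele fraction 0).
#' @param subclone_af_means mean allele fraction of each subclonal cluster.
#' @param subclone_weights mixture weights over clusters (sum to 1).
#' @param subclone_af_sd within-cluster standard deviation of true allele
#'   fractions; draws are truncated to `[0.05, 0.98]`.
#' @param loh_fraction fraction of the germline-escapee sites placed in a
#'   simulated loss-of-heterozygosity region (tumor allele fraction near 1,
#'   normal 0.5).
#' @param germline_pop_freq probability that a given sample is heterozygous
#'   at a shared germline panel site.
#' @param n_anchor number of somatic sites flagged as a previously
#'   validated "anchor" set; anchors are drawn from the highest-AF cluster.
#' @param seq_error per-base miscall probability in `[0, 0.1]`.
#' @param seed integer seed controlling cohort generation.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_somatic = 250,
                          n_germline = 19,
                          n_germline_escapee = 0,
                          n_null_candidates = 0,
                          subclone_af_means = c(0.2, 0.45),
                          subclone_weights = c(0.5, 0.5),
                          subclone_af_sd = 0.04,
                          loh_fraction = 0,
                          germline_pop_freq = 1,
                          n_anchor = 0,
                          seq_error = 0.001,
                          seed = 1L) {
  stopifnot(
    length(subclone_af_means) == length(subclone_weights),
    all(subclone_af_means > 0), all(subclone_af_means <= 1),
    abs(sum(subclone_weights) - 1) < 1e-9, all(subclone_weights >= 0),
    seq_error >= 0, seq_error <= 0.1,
    loh_fraction >= 0, loh_fraction <= 1,
    germline_pop_freq >= 0, germline_pop_freq <= 1,
    n_somatic >= 0, n_germline >= 0,
    n_germline_escapee >= 0, n_null_candidates >= 0
  )
  if (n_anchor > n_somatic) {
    stop("configuration error: n_anchor exceeds n_somatic")
  }
  if (loh_fraction > 0 && n_germline_escapee == 0 && loh_fraction * n_germline > n_germline) {
    stop("configuration error: more LOH SNPs requested than germline SNPs")
  }
  structure(list(
    n_somatic = n_somatic, n_germline = n_germline,
    n_germline_escapee = n_germline_escapee,
    n_null_candidates = n_null_candidates,
    subclone_af_means = subclone_af_means,
    subclone_weights = subclone_weights,
    subclone_af_sd = subclone_af_sd,
    loh_fraction = loh_fraction,
    germline_pop_freq = germline_pop_freq,
    n_anchor = n_anchor, seq_error = seq_error,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# draw subclonal true allele fractions from the cluster mixture,
# truncated to [0.05, 0.98] (a detectable-subclone floor and a ceiling
# short of full clonality with normal-cell contamination)
draw_subclonal_af <- function(n, config, cluster = NULL) {
  if (n == 0) return(numeric(0))
  if (is.null(cluster)) {
    cluster <- sample.int(length(config$subclone_af_means), n, replace = TRUE,
                          prob = config$subclone_weights)
  }
  af <- rnorm(n, config$subclone_af_means[cluster], config$subclone_af_sd)
  out_of_range <- which(af < 0.05 | af > 0.98)
  while (length(out_of_range)) {
    af[out_of_range] <- rnorm(length(out_of_range),
                              config$subclone_af_means[cluster[out_of_range]],
                              config$subclone_af_sd)
    out_of_range <- which(af < 0.05 | af > 0.98)
  }
  af
}

random_alleles <- function(n) {
  ref <- sample(DNA_BASES, n, replace = TRUE)
  shift <- sample.int(3, n, replace = TRUE)
  alt <- DNA_BASES[(match(ref, DNA_BASES) - 1 + shift) %% 4 + 1]
  list(ref = ref, alt = alt)
}

new_sites <- function(n, pos_start, chrom = "chr1", spacing = 50) {
  al <- random_alleles(n)
  data.frame(chrom = chrom,
             pos = pos_start + spacing * seq_len(n),
             ref = al$ref, alt = al$alt,
             stringsAsFactors = FALSE)
}

#' Generate per-sample ground truth for a synthetic cohort
#'
#' Produces one truth row per (sample, site) giving the true tumor and
#' normal allele fractions and a label in `{somatic, germline, null}`.
#' Somatic sites are private to one sample; germline panel sites are shared
#' across samples with population frequency `germline_pop_freq`.  The
#' generation is deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param sample_ids character vector of sample identifiers.
#' @param germline_sites optional data frame of already-generated shared
#'   germline panel sites (`chrom`, `pos`, `ref`, `alt`), so that several
#'   cohorts can share one panel.
#' @param pos_offset first genomic position offset for newly generated
#'   sites (lets several cohorts occupy disjoint coordinates).
#' @return data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `label`, `true_af_tumor`, `true_af_normal`, `panel`, `anchor`;
#'   attribute `next_pos` carries the next free position offset and
#'   attribute `germline_sites` the shared panel.
#' @export
generate_cohort <- function(config, sample_ids = "S1",
                            germline_sites = NULL, pos_offset = 0) {
  stopifnot(inherits(config, "cohort_config"), length(sample_ids) >= 1)
  with_seed_or_not(config$seed, {
    pos <- pos_offset
    if (is.null(germline_sites) && config$n_germline > 0) {
      germline_sites <- new_sites(config$n_germline, pos)
      pos <- max(germline_sites$pos)
    }
    rows <- list()
    for (sid in sample_ids) {
      # shared heterozygous panel SNPs
      if (!is.null(germline_sites) && nrow(germline_sites)) {
        het <- runif(nrow(germline_sites)) <= config$germline_pop_freq
        if (any(het)) {
          g <- germline_sites[het, , drop = FALSE]
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, g,
            label = "germline", true_af_tumor = 0.5, true_af_normal = 0.5,
            panel = TRUE, anchor = FALSE, stringsAsFactors = FALSE)
        }
      }
      # private somatic SNVs in subclonal clusters
      if (config$n_somatic > 0) {
        s <- new_sites(config$n_somatic, pos)
        pos <- max(s$pos)
        cluster <- sample.int(length(config$subclone_af_means),
                              config$n_somatic, replace = TRUE,
                              prob = config$subclone_weights)
        anchor <- rep(FALSE, config$n_somatic)
        if (config$n_anchor > 0) {
          anchor[seq_len(config$n_anchor)] <- TRUE
          cluster[seq_len(config$n_anchor)] <- which.max(config$subclone_af_means)
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, s,
          label = "somatic",
          true_af_tumor = draw_subclonal_af(config$n_somatic, config, cluster),
          true_af_normal = 0,
          panel = FALSE, anchor = anchor, stringsAsFactors = FALSE)
      }
      # germline variants posing as somatic candidates (diagonal pattern),
      # a fraction of them in a simulated LOH region (tumor AF near 1)
      if (config$n_germline_escapee > 0) {
        e <- new_sites(config$n_germline_escapee, pos)
        pos <- max(e$pos)
        n_loh <- round(config$loh_fraction * config$n_germline_escapee)
        tumor_af <- rep(0.5, config$n_germline_escapee)
        if (n_loh > 0) tumor_af[seq_len(n_loh)] <- runif(n_loh, 0.92, 1)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, e,
          label = "germline", true_af_tumor = tumor_af, true_af_normal = 0.5,
          panel = FALSE, anchor = FALSE, stringsAsFactors = FALSE)
      }
      # candidate sites with no true variant (upstream false positives)
      if (config$n_null_candidates > 0) {
        z <- new_sites(config$n_null_candidates, pos)
        pos <- max(z$pos)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, z,
          label = "null", true_af_tumor = 0, true_af_normal = 0,
          panel = FALSE, anchor = FALSE, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    attr(truth, "next_pos") <- pos
    attr(truth, "germline_sites") <- germline_sites
    truth
  })
}

#' Pool specification: members and mixing weights
#'
#' @param member_ids sample identifiers in the pool.
#' @param weights mixing proportions (default equal); must be non-negative
#'   and sum to 1 within `1e-9`.
#' @return list of class `pool_spec` with elements `member_ids`, `weights`
#'   and pool size `n`.
#' @export
pool_spec <- function(member_ids, weights = NULL) {
  n <- length(member_ids)
  stopifnot(n >= 1, !anyDuplicated(member_ids))
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  structure(list(member_ids = member_ids, weights = weights, n = n),
            class = "pool_spec")
}

#' Expected allele fraction of a weighted pool at one site
#'
#' The pooled allele fraction is the mixing-weight average of the member
#' allele fractions; with equal weights this reduces to the individual
#' allele fraction divided by the pool size.
#'
#' @param pool a [pool_spec()].
#' @param afs one allele fraction per pool member, in member order.
#' @return the pooled allele fraction `sum(weights * afs)`.
#' @export
true_pool_af <- function(pool, afs) {
  stopifnot(inherits(pool, "pool_spec"))
  if (length(afs) != pool$n) {
    stop("expected ", pool$n, " member allele fractions, got ", length(afs))
  }
  sum(pool$weights * afs)
}

#' Per-site depth model
#'
#' Depths are drawn from a negative binomial (gamma-mixed Poisson) with the
#' given mean and dispersion; `dispersion = 0` is the degenerate
#' equal-coverage limit.  Presets encode the ordinal evenness difference
#' between genomic DNA and whole-genome-amplified DNA: wgaDNA coverage is
#' more uneven.
#'
#' @param mean_depth positive mean depth.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives constant depths.
#' @param material `"gDNA"` or `"wgaDNA"` (annotation only).
#' @return list of class `depth_model`.
#' @export
depth_model <- function(mean_depth, dispersion, material = c("gDNA", "wgaDNA")) {
  material <- match.arg(material)
  stopifnot(mean_depth > 0, dispersion >= 0)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 material = material), class = "depth_model")
}

#' @rdname depth_model
#' @param preset_material which preset to return.
#' @export
depth_model_preset <- function(preset_material = c("gDNA", "wgaDNA"),
                               mean_depth = NULL) {
  preset_material <- match.arg(preset_material)
  if (preset_material == "gDNA") {
    depth_model(mean_depth %||% 1400, 0.15, "gDNA")
  } else {
    depth_model(mean_depth %||% 1550, 0.60, "wgaDNA")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-site sequencing depths
#'
#' @param model a [depth_model()].
#' @param n_sites number of sites.
#' @param seed optional seed (deterministic given seed).
#' @return integer vector of depths (>= 0).
#' @export
simulate_depths <- function(model, n_sites, seed = NULL) {
  stopifnot(inherits(model, "depth_model"), n_sites > 0)
  with_seed_or_not(seed, {
    if (model$dispersion <= 0) {
      rep(as.integer(round(model$mean_depth)), n_sites)
    } else {
      rnbinom(n_sites, mu = model$mean_depth, size = 1 / model$dispersion)
    }
  })
}

#' Simulate read counts at sites with known true allele fractions
#'
#' The alternate-read count is `Binomial(depth, p)` with
#' `p = af * (1 - e) + (1 - af) * e / 3` for per-base miscall probability
#' `e` (miscalls split uniformly over the three non-true bases); reads
#' supporting neither allele arise from the remaining reads at rate
#' `2 e / 3`.  Counts always conserve depth.
#'
#' @param true_af true allele fraction(s) in `[0, 1]` (vectorized).
#' @param depth per-site depth(s) (recycled against `true_af`).
#' @param seq_error per-base miscall probability in `[0, 0.1]`.
#' @param seed optional seed.
#' @return data frame with `ref_count`, `alt_count`, `other_count`, `depth`.
#' @export
simulate_site_counts <- function(true_af, depth, seq_error = 0, seed = NULL) {
  stopifnot(all(true_af >= 0), all(true_af <= 1), all(depth >= 0),
            seq_error >= 0, seq_error <= 0.1)
  n <- max(length(true_af), length(depth))
  true_af <- rep_len(true_af, n)
  depth <- rep_len(as.integer(round(depth)), n)
  with_seed_or_not(seed, {
    p_alt <- true_af * (1 - seq_error) + (1 - true_af) * seq_error / 3
    alt <- rbinom(n, depth, p_alt)
    other <- rbinom(n, depth - alt, 2 * seq_error / 3)
    data.frame(ref_count = depth - alt - other, alt_count = alt,
               other_count = other, depth = depth)
  })
}

# per-member tumor (or normal) allele fractions over a site universe;
# samples without a truth row at a site contribute 0
member_af_matrix <- function(truth, member_ids, sites,
                             tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  col <- if (tissue == "tumor") "true_af_tumor" else "true_af_normal"
  keys <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  m <- matrix(0, nrow = nrow(sites), ncol = length(member_ids),
              dimnames = list(NULL, member_ids))
  for (sid in member_ids) {
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    idx <- match(variant_key(tr$chrom, tr$pos, tr$ref, tr$alt), keys)
    ok <- !is.na(idx)
    m[idx[ok], sid] <- tr[[col]][ok]
  }
  m
}

#' Simulate one capture experiment (individual sample or pool)
#'
#' Composes the truth, mixing, depth and count models into a
#' count-table-compatible record set.  The site universe is the union of
#' the member samples' truth sites plus any background sites.  Pool mixing
#' weights can be perturbed around `stock_weights` by a symmetric Dirichlet
#' with concentration `weight_concentration`, emulating quantification and
#' pipetting error; replicate experiments share stock weights but draw
#' independent perturbations and counts.
#'
#' @param truth cohort truth from [generate_cohort()] (rows for all pool
#'   members must be present, or absent sites are taken as allele
#'   fraction 0).
#' @param pool a [pool_spec()]; a single-member pool is an individual
#'   sample experiment.
#' @param model a [depth_model()].
#' @param config the [cohort_config()] (supplies `seq_error`).
#' @param id experiment identifier.
#' @param kind `"tumor"`, `"normal"` or `"pool"`.
#' @param tissue which truth allele fraction to sequence (`"tumor"` for
#'   tumor material and pools, `"normal"` for matched normals).
#' @param replicate_of optional id of the experiment this replicates.
#' @param background_sites optional data frame (`chrom`, `pos`, `ref`,
#'   `alt`) of variant-free target-region sites included in the readout.
#' @param stock_weights realized composition of the pooled DNA stock
#'   (default: the nominal `pool$weights`).
#' @param weight_concentration Dirichlet concentration of the per-capture
#'   mixing perturbation; `NULL` uses `stock_weights` exactly.
#' @param seed optional seed for this experiment's substream.
#' @return list with `experiment` (metadata row), `counts` (count-table
#'   rows incl. `depth`), `weights` (realized mixing weights) and
#'   `true_af` (per-site pooled truth, in `counts` row order).
#' @export
simulate_experiment <- function(truth, pool, model, config,
                                id, kind = c("pool", "tumor", "normal"),
                                tissue = c("tumor", "normal"),
                                replicate_of = NA_character_,
                                background_sites = NULL,
                                stock_weights = NULL,
                                weight_concentration = 150,
                                seed = NULL) {
  kind <- match.arg(kind)
  tissue <- match.arg(tissue)
  stopifnot(inherits(pool, "pool_spec"), inherits(model, "depth_model"),
            inherits(config, "cohort_config"))
  missing_members <- setdiff(pool$member_ids, unique(truth$sample_id))
  if (length(missing_members)) {
    stop("pool member(s) absent from truth: ",
         paste(missing_members, collapse = ", "))
  }
  member_truth <- truth[truth$sample_id %in% pool$member_ids, , drop = FALSE]
  sites <- unique(member_truth[c("chrom", "pos", "ref", "alt")])
  if (!is.null(background_sites) && nrow(background_sites)) {
    sites <- unique(rbind(sites, background_sites[c("chrom", "pos", "ref", "alt")]))
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  with_seed_or_not(seed, {
    w <- stock_weights %||% pool$weights
    stopifnot(length(w) == pool$n, abs(sum(w) - 1) < 1e-6)
    if (!is.null(weight_concentration) && pool$n > 1) {
      g <- rgamma(pool$n, shape = weight_concentration * w)
      w <- g / sum(g)
    }
    afm <- member_af_matrix(truth, pool$member_ids, sites, tissue)
    pooled_af <- as.numeric(afm %*% w)
    depths <- simulate_depths(model, nrow(sites))
    cnt <- simulate_site_counts(pooled_af, depths, config$seq_error)
    counts <- cbind(
      data.frame(experiment_id = id, material = model$material, kind = kind,
                 pool_size = pool$n, stringsAsFactors = FALSE),
      sites, cnt)
    list(
      experiment = data.frame(id = id, material = model$material, kind = kind,
                              pool_size = pool$n, replicate_of = replicate_of,
                              stringsAsFactors = FALSE),
      counts = counts, weights = w, true_af = pooled_af)
  })
}
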