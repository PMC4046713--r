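# Configuration-driven end-to-end runner: simulate (or load) count tables,
# then run somatic validation -> pool detection -> de novo calling ->
# concordance/evenness metrics, and emit a consolidated report.

#' Default run configuration
#'
#' Describes the default simulated study: two whole-genome-sequenced
#' leukemia patients with matched normals (genomic DNA and whole-genome-
#' amplified tumor DNA), fourteen additional uncharacterized samples, and
#' non-indexed pools of two, five and ten samples, each prepared in
#' replicate.  The two larger pools over-represent their focal sample by a
#' factor 1.2 (stock weights 0.24 and 0.12 against nominal 0.20 and 0.10),
#' emulating DNA-quantification inaccuracy; the skew is a property of the
#' pooled stock and therefore shared between replicates, while pipetting
#' noise and sequencing are drawn independently per capture.
#'
#' @param seed master seed; every stochastic component draws a substream
#'   from it.
#' @return a nested configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    mode = "simulate",
    master_seed = as.integer(seed),
    seq_error = 0.001,
    n_background = 1500,
    n_germline_panel = 19,
    unknown_germline_freq = 0.5,
    depth = list(
      gDNA = list(mean_depth = 1400, dispersion = 0.15),
      wgaDNA = list(mean_depth = 1550, dispersion = 0.60)),
    patients = list(
      ALL1 = list(sample = "ALL1", n_somatic = 227, n_escapee = 250,
                  n_null = 249, loh_fraction = 0, n_anchor = 15,
                  tumor_exp = "ALL1_gDNA", normal_exp = "Normal1_gDNA",
                  wga_exp = "ALL1_wgaDNA"),
      ALL2 = list(sample = "ALL2", n_somatic = 305, n_escapee = 240,
                  n_null = 240, loh_fraction = 0.3, n_anchor = 15,
                  tumor_exp = "ALL2_gDNA", normal_exp = "Normal2_gDNA",
                  wga_exp = "ALL2_wgaDNA")),
    unknown_samples = sprintf("U%02d", 1:14),
    n_somatic_unknown = 2,
    pipetting_concentration = 5000,
    pools = list(
      list(id = "ALL1_pool2", focal = "ALL1", other_patient = "ALL2",
           members = c("ALL1", "U01"), focal_weight = NA),
      list(id = "ALL2_pool5", focal = "ALL2", other_patient = "ALL1",
           members = c("ALL2", sprintf("U%02d", 2:5)), focal_weight = 0.24),
      list(id = "ALL1_pool10", focal = "ALL1", other_patient = "ALL2",
           members = c("ALL1", sprintf("U%02d", 6:14)), focal_weight = 0.12)),
    thresholds = list(
      min_tumor_af = 0.1, max_normal_af = 0.01, min_depth = 30,
      detection_numerator = 0.05,
      denovo = list(expected_numerator = 0.5, window_low_factor = 0.5,
                    window_high_factor = 2, per_sample_min_depth = 30,
                    cross_experiment_max_af = 0.01, min_cross_depth = 30)),
    paths = NULL)
}

validate_run_config <- function(config) {
  stopifnot(is.list(config), config$mode %in% c("simulate", "analyze"))
  known <- c(vapply(config$patients, `[[`, "", "sample"),
             config$unknown_samples)
  for (p in config$pools) {
    unknown <- setdiff(p$members, known)
    if (length(unknown)) {
      stop("configuration error: pool '", p$id,
           "' references unknown sample(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!(p$focal %in% p$members)) {
      stop("configuration error: focal sample of pool '", p$id,
           "' is not among its members")
    }
  }
  if (config$mode == "analyze") {
    needed <- c("counts", "panel", "blacklist")
    have <- names(config$paths)
    if (!all(needed %in% have)) {
      stop("configuration error: analyze mode needs paths$",
           paste(setdiff(needed, have), collapse = ", paths$"))
    }
  }
  invisible(config)
}

pool_stock_weights <- function(p) {
  n <- length(p$members)
  if (is.null(p$focal_weight) || is.na(p$focal_weight)) {
    rep(1 / n, n)
  } else {
    w <- rep((1 - p$focal_weight) / (n - 1), n)
    w[match(p$focal, p$members)] <- p$focal_weight
    w
  }
}

#' Simulate the full default study
#'
#' Generates ground truth for all samples, the shared heterozygous SNP
#' panel (which doubles as the known-polymorphism blacklist), background
#' target-region sites, and simulated count tables for every experiment in
#' the roster (individual gDNA tumor/normal pairs, wgaDNA tumor
#' duplicates, and pools of 2/5/10 with replicates).
#'
#' @param config configuration from [default_run_config()].
#' @return list with `truth`, `counts` (one combined count table),
#'   `experiments` (metadata), `panel_sites`, `blacklist`,
#'   `background_sites` and `stock_weights` per pool.
#' @export
simulate_study <- function(config = default_run_config()) {
  validate_run_config(config)
  master <- config$master_seed
  dm <- function(material) depth_model(config$depth[[material]]$mean_depth,
                                       config$depth[[material]]$dispersion,
                                       material)
  truths <- list()
  panel <- NULL
  pos <- 0
  for (pid in names(config$patients)) {
    p <- config$patients[[pid]]
    cc <- cohort_config(
      n_somatic = p$n_somatic, n_germline = config$n_germline_panel,
      n_germline_escapee = p$n_escapee, n_null_candidates = p$n_null,
      loh_fraction = p$loh_fraction, n_anchor = p$n_anchor,
      germline_pop_freq = 1, seq_error = config$seq_error,
      seed = derive_seed(master, paste0("cohort/", pid)))
    tr <- generate_cohort(cc, p$sample, germline_sites = panel,
                          pos_offset = pos)
    panel <- attr(tr, "germline_sites")
    pos <- attr(tr, "next_pos")
    truths[[pid]] <- tr
  }
  if (length(config$unknown_samples)) {
    cc_u <- cohort_config(
      n_somatic = config$n_somatic_unknown,
      n_germline = config$n_germline_panel,
      germline_pop_freq = config$unknown_germline_freq,
      seq_error = config$seq_error,
      seed = derive_seed(master, "cohort/unknown"))
    tr_u <- generate_cohort(cc_u, config$unknown_samples,
                            germline_sites = panel, pos_offset = pos)
    pos <- attr(tr_u, "next_pos")
    truths$unknown <- tr_u
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  background <- with_seed_or_not(
    derive_seed(master, "background"),
    new_sites(config$n_background, pos))
  blacklist <- panel[c("chrom", "pos")]
  # the capture design is fixed: every experiment reads out every candidate
  # site of every sample plus the variant-free background target sites
  design_sites <- unique(rbind(truth[c("chrom", "pos", "ref", "alt")],
                               background))

  base_cc <- cohort_config(seq_error = config$seq_error,
                           seed = derive_seed(master, "noise"))
  experiments <- list()
  counts <- list()
  add_exp <- function(id, members, material, kind, tissue,
                      replicate_of = NA_character_, stock_weights = NULL,
                      concentration = NULL) {
    sim <- simulate_experiment(
      truth, pool_spec(members), dm(material), base_cc,
      id = id, kind = kind, tissue = tissue, replicate_of = replicate_of,
      background_sites = design_sites, stock_weights = stock_weights,
      weight_concentration = concentration,
      seed = derive_seed(master, paste0("exp/", id)))
    experiments[[id]] <<- sim$experiment
    counts[[id]] <<- sim$counts
  }
  for (pid in names(config$patients)) {
    p <- config$patients[[pid]]
    add_exp(p$tumor_exp, p$sample, "gDNA", "tumor", "tumor")
    add_exp(p$normal_exp, p$sample, "gDNA", "normal", "normal")
    add_exp(p$wga_exp, p$sample, "wgaDNA", "tumor", "tumor")
  }
  for (p in config$pools) {
    stock <- pool_stock_weights(p)
    rep_id <- paste0(p$id, "_rep")
    add_exp(p$id, p$members, "gDNA", "pool", "tumor",
            stock_weights = stock,
            concentration = config$pipetting_concentration)
    add_exp(rep_id, p$members, "gDNA", "pool", "tumor",
            replicate_of = p$id, stock_weights = stock,
            concentration = config$pipetting_concentration)
  }
  list(truth = truth,
       counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
       experiments = do.call(rbind, c(experiments, list(make.row.names = FALSE))),
       panel_sites = panel, blacklist = blacklist,
       background_sites = background)
}

exp_counts <- function(counts, id) {
  counts[counts$experiment_id == id, , drop = FALSE]
}

drop_sites <- function(counts, sites) {
  counts[!(site_key(counts$chrom, counts$pos) %in%
             site_key(sites$chrom, sites$pos)), , drop = FALSE]
}

keep_sites <- function(counts, sites) {
  counts[site_key(counts$chrom, counts$pos) %in%
           site_key(sites$chrom, sites$pos), , drop = FALSE]
}

#' Run the full pipeline
#'
#' In `simulate` mode, generates the study described by the configuration
#' and analyzes it; in `analyze` mode, reads a previously written count
#' table (plus the heterozygous-SNP panel and blacklist site lists named
#' in `config$paths`) and produces the identical analysis.  The run is
#' deterministic given `config$master_seed`.
#'
#' @param config configuration list (see [default_run_config()]).
#' @param outdir optional output directory; when given, all per-module
#'   TSV/JSON artifacts and the resolved configuration are written there.
#' @return a `pool_run_report`: list with per-patient validation results,
#'   heterozygous-SNP deviations, gDNA/wgaDNA concordance, per-experiment
#'   evenness, per-pool detection results (confusion matrix, FDR, median
#'   ratio, rescaling check, de novo calls), the replicate-concordant de
#'   novo call set, and a Table-style summary.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  validate_run_config(config)
  thr <- config$thresholds
  vt <- validation_thresholds(thr$min_tumor_af, thr$max_normal_af,
                              thr$min_depth)

  if (config$mode == "simulate") {
    study <- simulate_study(config)
    counts <- study$counts
    panel <- study$panel_sites
    blacklist <- study$blacklist
  } else {
    counts <- read_count_table(config$paths$counts)
    panel <- read_site_list(config$paths$panel, "tsv")
    blacklist <- read_site_list(config$paths$blacklist, "tsv")
    study <- NULL
  }
  counts <- with_allele_fractions(counts)

  # --- somatic validation per patient (candidates = non-panel sites) ---
  validation <- list()
  wga_validation <- list()
  for (pid in names(config$patients)) {
    p <- config$patients[[pid]]
    tum <- drop_sites(exp_counts(counts, p$tumor_exp), panel)
    nor <- drop_sites(exp_counts(counts, p$normal_exp), panel)
    validation[[pid]] <- validate_cohort(tum, nor, vt)
    wga <- drop_sites(exp_counts(counts, p$wga_exp), panel)
    wga_validation[[pid]] <- validate_cohort(wga, nor, vt)
  }

  # --- heterozygous-SNP deviation and evenness per experiment ---
  exp_ids <- unique(counts$experiment_id)
  het_dev <- setNames(rep(NA_real_, length(exp_ids)), exp_ids)
  evenness <- list()
  for (id in exp_ids) {
    ec <- exp_counts(counts, id)
    pan <- keep_sites(ec, panel)
    pan <- pan[pan$depth >= thr$min_depth & !is.na(pan$af), , drop = FALSE]
    ind <- ec$kind[1] != "pool"
    if (nrow(pan) && ind) het_dev[id] <- het_snp_deviation(pan$af)
    evenness[[id]] <- data.frame(
      experiment_id = id, material = ec$material[1], kind = ec$kind[1],
      cv = coefficient_of_variation(ec$depth),
      gini = gini_index(ec$depth), n_sites = nrow(ec),
      stringsAsFactors = FALSE)
  }
  evenness <- do.call(rbind, c(evenness, list(make.row.names = FALSE)))

  # --- gDNA vs wgaDNA allele-fraction concordance per patient ---
  wga_concordance <- list()
  for (pid in names(config$patients)) {
    p <- config$patients[[pid]]
    g <- exp_counts(counts, p$tumor_exp)
    w <- exp_counts(counts, p$wga_exp)
    g <- g[g$depth >= thr$min_depth, ]
    w <- w[w$depth >= thr$min_depth, ]
    m <- merge(g[c("chrom", "pos", "ref", "alt", "af")],
               w[c("chrom", "pos", "ref", "alt", "af")],
               by = c("chrom", "pos", "ref", "alt"),
               suffixes = c("_gdna", "_wga"))
    wga_concordance[[pid]] <- concordance_report(m$af_gdna, m$af_wga)
  }

  # --- pool detection, skew estimation and de novo calling ---
  somatic_sites <- lapply(validation, function(v) {
    v$status_table[v$status_table$status == "somatic", , drop = FALSE]
  })
  dn_cfg <- denovo_config(
    expected_numerator = thr$denovo$expected_numerator,
    window_low_factor = thr$denovo$window_low_factor,
    window_high_factor = thr$denovo$window_high_factor,
    per_sample_min_depth = thr$denovo$per_sample_min_depth,
    cross_experiment_max_af = thr$denovo$cross_experiment_max_af,
    min_cross_depth = thr$denovo$min_cross_depth,
    blacklist = blacklist)

  pools <- list()
  denovo_by_pool <- list()
  for (p in config$pools) {
    n <- length(p$members)
    dthr <- detection_threshold(thr$detection_numerator, n)
    positives <- somatic_sites[[p$focal]]
    negatives <- somatic_sites[[p$other_patient]]
    focal_gdna <- exp_counts(counts, config$patients[[p$focal]]$tumor_exp)
    rep_id <- paste0(p$id, "_rep")
    for (id in c(p$id, rep_id)) {
      pc <- exp_counts(counts, id)
      cm <- pool_confusion_matrix(pc, positives, negatives, dthr)
      fdr <- if (cm$tp + cm$fp > 0) false_discovery_rate(cm) else NA_real_
      # skew: observed pool AF vs expected individual AF / N at somatic sites
      pk <- keep_sites(pc, positives)
      pk <- pk[pk$depth > 0 & !is.na(pk$af), ]
      fg <- keep_sites(focal_gdna, positives)
      m <- merge(pk[c("chrom", "pos", "af")], fg[c("chrom", "pos", "af")],
                 by = c("chrom", "pos"), suffixes = c("_pool", "_ind"))
      m$expected <- expected_pool_af(m$af_ind, n)
      mr <- median_ratio(m$af_pool, m$expected)
      det0 <- detect_known(m$af_pool, dthr)
      det1 <- detect_known(scale_allele_fractions(m$af_pool, mr), dthr)
      dn <- denovo_scan(pc, n, dn_cfg, other_counts = counts,
                        exclude_experiments = c(p$id, rep_id), pool_id = id)
      pools[[id]] <- list(
        id = id, pool = p$id, n = n, replicate = id != p$id,
        threshold = dthr$value, cm = cm, fdr_percent = fdr, mr = mr,
        n_detected = sum(det0, na.rm = TRUE),
        n_changed_after_scaling = sum(det0 != det1, na.rm = TRUE),
        denovo = dn)
      denovo_by_pool[[id]] <- dn
    }
  }
  denovo_hc <- lapply(config$pools, function(p) {
    replicate_intersect(denovo_by_pool[[p$id]],
                        denovo_by_pool[[paste0(p$id, "_rep")]])
  })
  denovo_calls <- do.call(rbind, c(denovo_hc, list(make.row.names = FALSE)))

  report <- structure(list(
    config = config,
    validation = validation,
    wga_validation = wga_validation,
    het_deviation = het_dev,
    wga_concordance = wga_concordance,
    evenness = evenness,
    pools = pools,
    denovo_calls = denovo_calls,
    study = study
  ), class = "pool_run_report")
  report$summary_table <- summarize_report(report)

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Summarize a pipeline run as a detection-accuracy table
#'
#' One row per pool experiment with TP/TN/FP/FN tallies, the false
#' discovery rate rendered at one decimal, and the number of
#' replicate-concordant novel calls seen in that experiment.
#'
#' @param report a `pool_run_report` from [run_pipeline()].
#' @return data frame with columns `sample`, `tp`, `tn`, `fp`, `fn`,
#'   `fdr_percent`, `novel`, `replicate`.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "pool_run_report"))
  hc_keys <- character(0)
  if (!is.null(report$denovo_calls) && nrow(report$denovo_calls)) {
    hc <- report$denovo_calls[report$denovo_calls$high_confidence, ]
    hc_keys <- variant_key(hc$chrom, hc$pos, hc$ref, hc$alt)
  }
  rows <- lapply(report$pools, function(pl) {
    novel <- 0L
    if (nrow(pl$denovo)) {
      novel <- sum(variant_key(pl$denovo$chrom, pl$denovo$pos,
                               pl$denovo$ref, pl$denovo$alt) %in% hc_keys)
    }
    data.frame(
      sample = pl$id, tp = pl$cm$tp, tn = pl$cm$tn, fp = pl$cm$fp,
      fn = pl$cm$fn,
      fdr_percent = ifelse(is.na(pl$fdr_percent), NA_character_,
                           sprintf("%.1f", pl$fdr_percent)),
      novel = novel, replicate = pl$replicate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

# serialize the numeric content of a report for artifacts and
# determinism checks
report_summary_list <- function(report) {
  list(
    somatic_counts = lapply(report$validation, function(v) as.list(v$summary)),
    wga_somatic_counts = lapply(report$wga_validation,
                                function(v) as.list(v$summary)),
    het_deviation = as.list(report$het_deviation),
    wga_concordance = report$wga_concordance,
    pools = lapply(report$pools, function(pl) {
      list(n = pl$n, threshold = pl$threshold,
           tp = pl$cm$tp, tn = pl$cm$tn, fp = pl$cm$fp, fn = pl$cm$fn,
           excluded_pos = pl$cm$excluded_pos,
           excluded_neg = pl$cm$excluded_neg,
           fdr_percent = pl$fdr_percent, median_ratio = pl$mr,
           n_detected = pl$n_detected,
           n_changed_after_scaling = pl$n_changed_after_scaling,
           n_denovo = nrow(pl$denovo))
    }),
    denovo_high_confidence = sum(report$denovo_calls$high_confidence %||% FALSE)
  )
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$study)) {
    write_count_table(report$study$counts, file.path(outdir, "counts.tsv"))
    write_tsv(report$study$truth, file.path(outdir, "truth.tsv"))
    write_tsv(report$study$panel_sites[c("chrom", "pos")],
              file.path(outdir, "panel.tsv"))
    write_tsv(report$study$blacklist, file.path(outdir, "blacklist.tsv"))
  }
  for (pid in names(report$validation)) {
    write_tsv(report$validation[[pid]]$status_table,
              file.path(outdir, paste0("validation_", pid, ".tsv")))
  }
  write_tsv(report$evenness, file.path(outdir, "evenness.tsv"))
  for (id in names(report$pools)) {
    pl <- report$pools[[id]]
    write_tsv(pl$cm$classes, file.path(outdir, paste0("pool_", id, ".tsv")))
  }
  if (nrow(report$denovo_calls)) {
    write_tsv(report$denovo_calls, file.path(outdir, "denovo_calls.tsv"))
  }
  write_tsv(report$summary_table, file.path(outdir, "summary.tsv"))
  jsonlite::write_json(report_summary_list(report),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  yaml::write_yaml(report$config, file.path(outdir, "config_resolved.yaml"))
  invisible(outdir)
}

#' @export
print.pool_run_report <- function(x, ...) {
  cat("Pooled somatic SNV pipeline run (seed ", x$config$master_seed, ")\n",
      sep = "")
  for (pid in names(x$validation)) {
    s <- x$validation[[pid]]$summary
    cat(sprintf("  %s: %d somatic / %d candidates\n", pid, s["somatic"],
                sum(s)))
  }
  cat("Pool detection:\n")
  print(x$summary_table, row.names = FALSE)
  invisible(x)
}
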