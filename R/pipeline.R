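# End-to-end orchestration: simulate -> summits -> motifs -> classes ->
# controls -> enrichment -> co-occupancy -> specific sites -> ratios ->
# target genes -> signatures -> survival, with a JSON manifest.

#' Pipeline configuration
#'
#' Bundles every analysis parameter (defaults are the workflow's standard
#' values: summit windows +/-150 bp, TSS window 2 kb, upstream window 150
#' bp, motif p-value 1e-4, positional window 500 bp, CV bounds 5%/85%, GSS
#' threshold 0, adjusted-p cutoff 0.05, knockout drop fraction 0.5) with
#' the synthetic-data configuration and a root seed.
#'
#' @param seed Root seed; stage seeds are derived from it.
#' @param synth A [synth_config()]; defaults to `synth_config(seed = seed)`.
#' @param summit_half_width,tss_window_bp,upstream_bp,motif_pvalue
#'   Core genomic parameters (bp / probability).
#' @param positional_window_bp,positional_bin_bp Motif-position histogram.
#' @param control_bin_width Z-score bin width for matched controls.
#' @param smooth_bandwidth_bp Gaussian kernel SD for signal smoothing.
#' @param cv_low,cv_high Coefficient-of-variation filter bounds.
#' @param padj_cutoff Adjusted p-value cutoff for specific sites.
#' @param drop_fraction Knockout confirmation drop fraction.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            synth = NULL,
                            summit_half_width = 150,
                            tss_window_bp = 2000,
                            upstream_bp = 150,
                            motif_pvalue = 1e-4,
                            positional_window_bp = 500,
                            positional_bin_bp = 10,
                            control_bin_width = 0.1,
                            smooth_bandwidth_bp = 10,
                            cv_low = 0.05,
                            cv_high = 0.85,
                            padj_cutoff = 0.05,
                            drop_fraction = 0.5) {
  if (is.null(synth)) synth <- synth_config(seed = seed)
  cfg <- as.list(environment())
  with(cfg, stopifnot(
    summit_half_width > 0, tss_window_bp > 0, upstream_bp > 0,
    motif_pvalue > 0, motif_pvalue < 1, positional_window_bp > 0,
    positional_bin_bp > 0, control_bin_width > 0, smooth_bandwidth_bp > 0,
    cv_low >= 0, cv_low < cv_high, padj_cutoff > 0, padj_cutoff < 1,
    drop_fraction > 0, drop_fraction < 1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Link peaks to proximal genes
#'
#' Pairs every peak with every gene having a TSS within `window_bp`
#' (inclusive edge distance, as in [classify_tss_proximity()]).
#'
#' @param peaks Interval data.frame.
#' @param tss TSS annotation data.frame.
#' @param window_bp Proximity window (default 2000).
#' @return data.frame with columns `peak` (row index into `peaks`) and
#'   `gene_id`.
#' @export
peak_gene_links <- function(peaks, tss, window_bp = 2000) {
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end + 1L))
  ts <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(tss$position + 1L - window_bp,
                                                tss$position + 1L + window_bp))
  ov <- GenomicRanges::findOverlaps(pk, ts)
  out <- unique(data.frame(peak = S4Vectors::queryHits(ov),
                           gene_id = tss$gene_id[S4Vectors::subjectHits(ov)],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every stage in order, writes each intermediate as a
#' tab-separated file under `outdir`, and returns (and writes) a manifest
#' listing files, parameters, the seed and per-file MD5 checksums. The run
#' is a pure function of the configuration, so identical configurations
#' yield byte-identical outputs and manifests.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param dataset Optional pre-generated [generate_dataset()] result
#'   matching `config$synth` (generated when `NULL`).
#' @return Invisibly, a list with the manifest, the dataset and key stage
#'   results (`summary` holds the headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  keep <- function(nm, path) files[nm] <<- path

  ## stage: simulate
  ds <- if (is.null(dataset)) generate_dataset(config$synth) else dataset
  data_files <- write_dataset(ds, file.path(outdir, "data"))
  motifs <- default_motifs()

  ## stage: summits (recompute YAP summits from the signal track, then
  ## summit windows and TSS annotation)
  yap <- ds$factor_peaks$YAP
  yap_called <- find_summits(yap[, c("chrom", "start", "end")], ds$tracks,
                             smooth_bandwidth_bp = config$smooth_bandwidth_bp)
  yap_called$name <- ds$peaks$peak_id
  windows <- adjust_to_summit_window(yap_called, config$summit_half_width)
  windows$proximity <- classify_tss_proximity(windows, ds$tss,
                                              config$tss_window_bp)
  keep("peaks_annotated", write_tsv(windows, file.path(outdir, "peaks_annotated.tsv")))

  ## stage: motifs (summit +/- half-width scan at the exact p threshold)
  seqs <- summit_window_sequences(ds, windows, config$summit_half_width)
  names(seqs) <- windows$name
  profiles <- scan_peaks(seqs, motifs, pvalue = config$motif_pvalue)
  best <- data.frame(peak_id = profiles$peak_id, profiles$best_raw,
                     check.names = FALSE)
  keep("motif_best_scores", write_tsv(best, file.path(outdir, "motif_best_scores.tsv")))
  nh <- data.frame(peak_id = profiles$peak_id, profiles$n_hits,
                   check.names = FALSE)
  keep("motif_hit_counts", write_tsv(nh, file.path(outdir, "motif_hit_counts.tsv")))

  ## stage: classify (+ positional histograms and composite spacing)
  classes <- classify_peaks(profiles)
  cls_df <- data.frame(peak_id = profiles$peak_id, class = as.character(classes),
                       stringsAsFactors = FALSE)
  keep("peak_classes", write_tsv(cls_df, file.path(outdir, "peak_classes.tsv")))
  seqs500 <- summit_window_sequences(ds, windows, config$positional_window_bp)
  prof500 <- scan_peaks(seqs500, motifs[c("AP1", "TEAD", "TEAD_DIMER",
                                          "STAT3", "NFKB")],
                        pvalue = config$motif_pvalue)
  hist_df <- do.call(rbind, lapply(prof500$motifs, function(m) {
    h <- positional_histogram(prof500, m, config$positional_window_bp,
                              config$positional_bin_bp)
    h$motif <- m
    h
  }))
  keep("positional_histograms", write_tsv(hist_df, file.path(outdir, "positional_histograms.tsv")))
  spac <- composite_spacing(profiles)
  keep("composite_spacing", write_tsv(
    data.frame(peak_id = names(spac), spacing_bp = as.numeric(spac)),
    file.path(outdir, "composite_spacing.tsv")))

  ## stage: matched controls
  yt_union <- windows[, c("chrom", "start", "end")]
  bound_idx <- GenomicRanges::countOverlaps(intervals_to_granges(ds$dhs),
                                            intervals_to_granges(yt_union)) > 0
  bound <- ds$dhs[bound_idx, , drop = FALSE]
  ctrl <- sample_matched_controls(bound, ds$dhs, yt_union,
                                  seed = config$seed + 1000L,
                                  bin_width = config$control_bin_width)
  keep("control_set", {
    fn <- file.path(outdir, "control_dhs.bed")
    write_dhs(ctrl$records, fn)
    jsonlite::write_json(list(seed = ctrl$seed, bin_width = ctrl$bin_width,
                              n = nrow(ctrl$records)),
                         file.path(outdir, "control_dhs.json"), auto_unbox = TRUE)
    fn
  })

  ## stage: enrichment vs matched controls
  ctr_center <- (ctrl$records$start + ctrl$records$end) %/% 2L
  ctr_df <- data.frame(chrom = ctrl$records$chrom, summit = ctr_center)
  ctr_seqs <- summit_window_sequences(ds, ctr_df, config$summit_half_width)
  names(ctr_seqs) <- sprintf("ctrl_%05d", seq_along(ctr_seqs))
  ctr_prof <- scan_peaks(ctr_seqs, motifs, pvalue = config$motif_pvalue)
  groups <- list(AP1 = "AP1", TEAD = c("TEAD", "TEAD_DIMER"),
                 STAT3 = "STAT3", CEBP = "CEBP", NFKB = "NFKB")
  enr <- do.call(rbind, lapply(names(groups), function(g) {
    e <- motif_enrichment(profiles, ctr_prof, groups[[g]])
    data.frame(motif = g, frac_target = e$frac_target,
               frac_control = e$frac_control, fold = e$fold,
               chisq = e$chisq, pvalue = e$pvalue)
  }))
  keep("motif_enrichment", write_tsv(enr, file.path(outdir, "motif_enrichment.tsv")))
  pair_names <- list(c("AP1", "TEAD"), c("AP1", "STAT3"), c("TEAD", "STAT3"),
                     c("TEAD", "CEBP"))
  coocc <- do.call(rbind, lapply(pair_names, function(pr) {
    co <- pairwise_cooccurrence(profiles, ctr_prof,
                                list(groups[[pr[1L]]], groups[[pr[2L]]]))
    data.frame(motif_a = pr[1L], motif_b = pr[2L],
               frac_target = co$frac_target, frac_control = co$frac_control,
               fold = co$fold)
  }))
  keep("cooccurrence", write_tsv(coocc, file.path(outdir, "motif_cooccurrence.tsv")))

  ## stage: summit-distance co-occupancy
  fps <- ds$factor_peaks
  prs <- utils::combn(names(fps), 2L)
  sdist <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    s <- summit_distance_summary(fps[[prs[1L, i]]], fps[[prs[2L, i]]],
                                 pair = prs[, i])
    data.frame(factor_a = prs[1L, i], factor_b = prs[2L, i],
               n_pairs = s$n, median_bp = s$median)
  }))
  keep("summit_distances", write_tsv(sdist, file.path(outdir, "summit_distances.tsv")))

  ## stage: paralog-specific sites + knockout confirmation
  db <- differential_binding(ds$counts$YAP, ds$counts$TAZ,
                             alpha = config$padj_cutoff)
  conf <- confirm_specific_sites(db$call, ds$ko$parent, ds$ko$yap_ko,
                                 ds$ko$taz_ko,
                                 drop_fraction = config$drop_fraction,
                                 peak_id = db$peak_id)
  db$confirmed <- conf$confirmed
  keep("specific_sites", write_tsv(db, file.path(outdir, "specific_sites.tsv")))

  ## stage: crosslink-ratio correlation (JUNB:TEAD vs motif scores)
  tead_best <- pmax(profiles$best_raw[, "TEAD"], profiles$best_raw[, "TEAD_DIMER"])
  r_ap1 <- crosslink_ratio_correlation(ds$crosslink$junb_signal,
                                       ds$crosslink$tead_signal,
                                       profiles$best_raw[, "AP1"])
  r_tead <- crosslink_ratio_correlation(ds$crosslink$junb_signal,
                                        ds$crosslink$tead_signal, tead_best)
  ratios <- data.frame(score = c("AP1", "TEAD"),
                       pearson_r = c(r_ap1$r, r_tead$r),
                       n = c(r_ap1$n, r_tead$n))
  keep("crosslink_ratios", write_tsv(ratios, file.path(outdir, "crosslink_ratios.tsv")))

  ## stage: target genes + differential-gene enrichment
  target_map <- assign_target_genes(windows, ds$tss, config$tss_window_bp)
  tge <- target_gene_enrichment(ds$diff_genes, names(target_map), target_map,
                                seed = config$seed + 2000L)
  keep("target_gene_enrichment", write_tsv(
    data.frame(n_diff_target = tge$n_diff_target,
               n_diff_nontarget = tge$n_diff_nontarget,
               n_ctrl_target = tge$n_ctrl_target,
               n_ctrl_nontarget = tge$n_ctrl_nontarget,
               chisq = tge$chisq, pvalue = tge$pvalue),
    file.path(outdir, "target_gene_enrichment.tsv")))

  ## stage: signatures + GSS + survival
  links <- peak_gene_links(windows, ds$tss, config$tss_window_bp)
  cv_keep <- cv_filter(ds$expression, config$cv_low, config$cv_high)
  modes <- c("AP1_only", "TEAD_only", "AP1_and_TEAD")
  surv_rows <- list()
  gss_tables <- list()
  for (mode in modes) {
    sig <- tryCatch(define_motif_signature(classes, links, mode),
                    error = function(e) NULL)
    if (is.null(sig)) next
    genes <- intersect(sig$genes, cv_keep)
    if (length(genes) == 0L) next
    g_tab <- gss(ds$expression, genes)
    gss_tables[[mode]] <- g_tab
    merged <- merge(g_tab, ds$survival, by = "patient")
    lr <- logrank_test(merged$time, merged$event, merged$group)
    km_hi <- km_estimate(merged$time[merged$group == "high"],
                         merged$event[merged$group == "high"])
    km_lo <- km_estimate(merged$time[merged$group == "low"],
                         merged$event[merged$group == "low"])
    t_med <- median(merged$time)
    surv_rows[[mode]] <- data.frame(
      signature = mode, n_genes = length(genes),
      n_high = sum(merged$group == "high"), n_low = sum(merged$group == "low"),
      logrank_chisq = lr$statistic, logrank_p = lr$pvalue,
      surv_high_at_median_t = km_survival_at(km_hi, t_med),
      surv_low_at_median_t = km_survival_at(km_lo, t_med))
  }
  surv_df <- do.call(rbind, surv_rows)
  keep("survival_results", write_tsv(surv_df, file.path(outdir, "survival_results.tsv")))
  if (!is.null(gss_tables[[config$synth$signature_mode]])) {
    keep("gss", write_tsv(gss_tables[[config$synth$signature_mode]],
                          file.path(outdir, "gss.tsv")))
  }

  ## manifest with checksums (no timestamps: byte-identical across reruns)
  all_files <- c(data_files, files)
  manifest <- list(
    package = "peakmotifs",
    seed = config$seed,
    parameters = config[setdiff(names(config), "synth")],
    synth = unclass(config$synth),
    files = as.list(all_files),
    md5 = as.list(tools::md5sum(unname(all_files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## headline numbers
  class_recovery <- mean(as.character(classes) == ds$truth$peaks$class)
  summary <- list(
    class_counts = table(classes),
    class_recovery = class_recovery,
    median_summit_distance = median(sdist$median_bp),
    enrichment = enr,
    crosslink_r = setNames(ratios$pearson_r, ratios$score),
    n_confirmed_yap = sum(conf$confirmed == "YAP_specific"),
    n_confirmed_taz = sum(conf$confirmed == "TAZ_specific"),
    survival = surv_df)
  invisible(list(manifest = manifest, dataset = ds, profiles = profiles,
                 classes = classes, differential = db, confirmation = conf,
                 control_set = ctrl, summary = summary))
}
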