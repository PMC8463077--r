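# Seeded synthetic-data generator with recorded ground truth.
#
# Emulates the statistical structure the downstream analyses assume: peak
# sets of several factors with coinciding (jittered) summits, planted motif
# instances at controlled frequencies and offsets, per-peak signal whose
# JUNB:TEAD log-ratio tracks the AP-1 motif score, replicate
# negative-binomial counts with planted paralog-specific sites and matching
# knockout drops, a DHS atlas with accessibility Z-scores, a TSS
# annotation, and expression + survival data with a hazard effect planted
# on the high-GSS group of a motif-class signature.

#' Bundled synthetic motif set
#'
#' Six sharpened 13-bp PWMs (AP-1, TEAD monomer, TEAD dimer, STAT3, CEBP,
#' NF-kB) whose consensus embeds the canonical core of each factor's motif.
#' They are synthetic stand-ins for database motifs, deliberately
#' high-information so that instances sampled from the PWM are reliably
#' recovered at the `1e-4` scanning threshold while background hits stay
#' rare.
#'
#' @param pseudocount Passed to [pwm()] (default 0.01).
#' @return Named list of [pwm()] objects.
#' @export
default_motifs <- function(pseudocount = 0.01) {
  path <- system.file("extdata", "motifs", "synthetic_motifs.jaspar",
                      package = "peakmotifs")
  if (!nzchar(path)) stop("bundled motif file not found")
  read_jaspar(path, pseudocount = pseudocount)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the study conditions the package's analyses are
#' exercised under; see the methods vignette for the rationale of each
#' value.
#'
#' @param seed Root RNG seed; the whole dataset is a deterministic function
#'   of it.
#' @param n_chroms,chrom_length Genome shape (i.i.d. uniform background
#'   sequence).
#' @param n_peaks Number of co-activator binding sites.
#' @param class_mixture Named probabilities over the motif-class labels.
#' @param summit_jitter_sd Per-factor summit jitter (bp, Normal).
#' @param peak_half_width Summit window half-width (bp).
#' @param motif_offset_max Planted motif centers are uniform on
#'   `[-motif_offset_max, motif_offset_max]` around the true summit.
#' @param motif_pvalue Scanning match p-value.
#' @param tead_dimer_prob Probability a planted TEAD instance uses the
#'   dimer PWM instead of the monomer.
#' @param factors ChIP'd factor names.
#' @param signal_baseline Baseline ChIP signal level (arbitrary units).
#' @param signal_lnorm_sd Log-normal spread of per-peak amplitudes.
#' @param signal_bump_sd Gaussian footprint of the signal bump (bp).
#' @param crosslink_target_cor Planted Pearson correlation between the
#'   JUNB:TEAD log2 signal ratio and the AP-1 best raw score; when `NULL`,
#'   `crosslink_ratio_slope`/`crosslink_noise_sd` are used directly.
#' @param crosslink_lr_sd Total standard deviation of the planted log-ratio
#'   when `crosslink_target_cor` is used.
#' @param crosslink_ratio_slope,crosslink_noise_sd Direct parameterization
#'   (log2-ratio per bit of AP-1 score; residual SD).
#' @param nb_mean,nb_dispersion,n_replicates Negative-binomial replicate
#'   counts for the YAP and TAZ ChIPs.
#' @param count_lnorm_sd Log-normal spread of per-peak count means.
#' @param n_specific_yap,n_specific_taz Planted paralog-specific site
#'   counts (defaults follow the confirmed site counts of the motivating
#'   study: 125 YAP, 450 TAZ).
#' @param specific_log2fc True log2 fold change at specific sites.
#' @param ko_drop Fraction of parental signal lost in the matching
#'   knockout at a specific site.
#' @param ko_noise_sd Log-normal noise SD on knockout/parental signals.
#' @param n_dhs Base number of atlas DHSs; every peak-bound DHS
#'   additionally receives `dhs_sibling_factor` non-bound atlas sites with
#'   identical Z-score, so matched sampling always has same-Z alternatives.
#' @param dhs_width DHS width (bp).
#' @param bound_z_mean,bound_z_sd Accessibility Z of peak-bound DHSs
#'   (Normal, truncated to mean +/- 2.5 sd).
#' @param dhs_sibling_factor Same-Z non-bound siblings per bound DHS.
#' @param gene_fraction Fraction of peaks assigned a proximal gene TSS.
#' @param n_background_genes Genes with TSSs far from any peak.
#' @param n_patients Cohort size for expression + survival.
#' @param expression_mean_log,expression_sd_log Log-normal gene baseline
#'   expression (TPM-like).
#' @param expression_noise_range Per-gene log-scale noise SD range
#'   (uniform), keeping CVs inside the 5-85% filter band.
#' @param signature_effect Log-scale loading of the patient latent factor
#'   on signature genes.
#' @param signature_mode Motif-class signature carrying the survival
#'   effect.
#' @param hazard_ratio Hazard multiplier for the high-GSS group.
#' @param base_hazard Baseline exponential hazard (per month).
#' @param censoring_fraction Target fraction of censored patients
#'   (independent exponential censoring, calibrated).
#' @param diff_gene_rate_target,diff_gene_rate_other Probability a
#'   target / non-target gene enters the differential gene list.
#' @return A `synth_config` list (validated).
#' @export
synth_config <- function(seed = 1,
                         n_chroms = 4,
                         chrom_length = 5200000L,
                         n_peaks = 5000,
                         class_mixture = c(AP1_only = 0.19, TEAD_only = 0.19,
                                           STAT3_only = 0.06, AP1_TEAD = 0.07,
                                           AP1_STAT3 = 0.04, TEAD_STAT3 = 0.04,
                                           AP1_TEAD_STAT3 = 0.02, none = 0.39),
                         summit_jitter_sd = 15,
                         peak_half_width = 150,
                         motif_offset_max = 100,
                         motif_pvalue = 1e-4,
                         tead_dimer_prob = 0.3,
                         factors = c("YAP", "TAZ", "JUNB", "TEAD", "STAT3"),
                         signal_baseline = 200,
                         signal_lnorm_sd = 0.4,
                         signal_bump_sd = 40,
                         crosslink_target_cor = 0.5,
                         crosslink_lr_sd = 1,
                         crosslink_ratio_slope = NULL,
                         crosslink_noise_sd = NULL,
                         nb_mean = 200,
                         nb_dispersion = 0.05,
                         n_replicates = 3,
                         count_lnorm_sd = 0.5,
                         n_specific_yap = 125,
                         n_specific_taz = 450,
                         specific_log2fc = 3,
                         ko_drop = 0.9,
                         ko_noise_sd = 0.2,
                         n_dhs = 20000,
                         dhs_width = 200,
                         bound_z_mean = 2,
                         bound_z_sd = 1,
                         dhs_sibling_factor = 3,
                         gene_fraction = 0.5,
                         n_background_genes = 400,
                         n_patients = 200,
                         expression_mean_log = log(50),
                         expression_sd_log = 0.7,
                         expression_noise_range = c(0.15, 0.45),
                         signature_effect = 0.5,
                         signature_mode = "AP1_only",
                         hazard_ratio = 2,
                         base_hazard = 0.02,
                         censoring_fraction = 0.2,
                         diff_gene_rate_target = 0.3,
                         diff_gene_rate_other = 0.05) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$class_mixture) - 1) < 1e-8,
            all(names(cfg$class_mixture) %in% MOTIF_CLASSES),
            cfg$n_peaks > 0, cfg$hazard_ratio > 0,
            cfg$n_specific_yap + cfg$n_specific_taz <= cfg$n_peaks,
            cfg$censoring_fraction >= 0, cfg$censoring_fraction < 1,
            cfg$summit_jitter_sd >= 0,
            cfg$signature_mode %in% c("AP1_only", "TEAD_only", "AP1_and_TEAD"))
  class(cfg) <- "synth_config"
  cfg
}

# Truncated normal via the inverse-CDF trick (deterministic given the RNG).
rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

# Sample one sequence instance from a PWM's (raw) probability rows.
sample_pwm_instance <- function(x) {
  paste(vapply(seq_len(x$width),
               function(j) sample(BASES, 1L, prob = x$probs[j, ]),
               character(1)), collapse = "")
}

# Classes -> planted motif names.
class_motifs <- function(label) {
  m <- character(0)
  if (grepl("AP1", label)) m <- c(m, "AP1")
  if (grepl("TEAD", label)) m <- c(m, "TEAD")
  if (grepl("STAT3", label)) m <- c(m, "STAT3")
  m
}

SIGNATURE_CLASS_MAP <- list(
  AP1_only = c("AP1_only", "AP1_STAT3"),
  TEAD_only = c("TEAD_only", "TEAD_STAT3"),
  AP1_and_TEAD = c("AP1_TEAD", "AP1_TEAD_STAT3"))

#' Generate a complete synthetic dataset with ground truth
#'
#' Deterministic given `config$seed`. See [synth_config()] for the moving
#' parts and the methods vignette for what the generator does and does not
#' emulate.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_dataset`: list with `config`, `genome`
#'   (named character vector), `peaks`, `factor_peaks`, `tracks` (YAP
#'   signal), `counts` (YAP/TAZ replicate matrices), `ko` (knockout
#'   signals), `crosslink` (JUNB/TEAD signals + AP-1 scores), `dhs`,
#'   `tss`, `expression`, `survival`, `diff_genes`, and `truth`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  motifs <- default_motifs()
  W <- motifs$AP1$width
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  L <- cfg$chrom_length
  reserve <- 60000L # tail region per chromosome kept free of peaks
  min_spacing <- 2L * (cfg$peak_half_width + cfg$motif_offset_max + 50L)

  # genome as per-chromosome character vectors (planting mutates slices)
  genome_v <- lapply(chroms, function(ch) sample(BASES, L, replace = TRUE))
  names(genome_v) <- chroms

  # peak layout: evenly spaced true summits, margins at both ends
  per_chrom <- diff(round(seq(0, cfg$n_peaks, length.out = cfg$n_chroms + 1)))
  usable <- L - reserve - 1000L
  peaks <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    n_c <- per_chrom[i]
    if (n_c == 0L) return(NULL)
    spacing <- usable %/% n_c
    if (spacing < min_spacing) {
      stop("chromosomes too short for ", cfg$n_peaks, " peaks: spacing ",
           spacing, " < ", min_spacing)
    }
    data.frame(chrom = chroms[i],
               true_summit = as.integer(1000L + spacing * (seq_len(n_c) - 1L) +
                                          spacing %/% 2L),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(peaks)
  peaks$peak_id <- sprintf("peak_%05d", seq_len(n))
  peaks$class <- sample(names(cfg$class_mixture), n, replace = TRUE,
                        prob = cfg$class_mixture)

  # plant motif instances: centers uniform around the true summit,
  # non-overlapping within a peak
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    wanted <- class_motifs(peaks$class[i])
    if (length(wanted) == 0L) next
    pw_names <- vapply(wanted, function(m) {
      if (m == "TEAD" && runif(1) < cfg$tead_dimer_prob) "TEAD_DIMER" else m
    }, character(1))
    repeat {
      centers <- as.integer(round(runif(length(pw_names), -cfg$motif_offset_max,
                                        cfg$motif_offset_max)))
      if (length(centers) == 1L || min(dist(centers)) >= W + 1L) break
    }
    inst <- vapply(pw_names, function(m) sample_pwm_instance(motifs[[m]]),
                   character(1))
    ch <- peaks$chrom[i]
    for (k in seq_along(pw_names)) {
      s0 <- peaks$true_summit[i] + centers[k] - (W - 1L) %/% 2L
      genome_v[[ch]][(s0 + 1L):(s0 + W)] <- strsplit(inst[k], "")[[1L]]
    }
    planted[[i]] <- data.frame(peak_id = peaks$peak_id[i], motif = pw_names,
                               center_offset = centers, instance = inst,
                               stringsAsFactors = FALSE, row.names = NULL)
  }
  planted <- do.call(rbind, planted)
  genome <- vapply(genome_v, paste, character(1), collapse = "")

  # per-factor jittered summits and fixed-width peak windows
  hw <- cfg$peak_half_width
  factor_peaks <- lapply(cfg$factors, function(f) {
    sm <- peaks$true_summit +
      as.integer(round(rnorm(n, 0, cfg$summit_jitter_sd)))
    data.frame(chrom = peaks$chrom, start = pmax(0L, sm - hw),
               end = sm + hw + 1L, name = paste0(f, "_", peaks$peak_id),
               score = NA_real_, summit = sm, stringsAsFactors = FALSE)
  })
  names(factor_peaks) <- cfg$factors

  # AP-1 best raw score per true-summit window (drives the crosslink ratio)
  win_seq <- substring(genome[peaks$chrom], peaks$true_summit - hw + 1L,
                       peaks$true_summit + hw + 1L)
  names(win_seq) <- peaks$peak_id
  prof_ap1 <- scan_peaks(win_seq, motifs["AP1"], pvalue = cfg$motif_pvalue)
  ap1_score <- prof_ap1$best_raw[, "AP1"]

  # JUNB:TEAD crosslinking ratio model
  s_c <- ap1_score - mean(ap1_score)
  rho <- cfg$crosslink_target_cor
  if (!is.null(rho)) {
    if (rho == 0) {
      slope <- 0
      noise_sd <- cfg$crosslink_lr_sd
    } else {
      slope <- rho * cfg$crosslink_lr_sd / sd(s_c)
      noise_sd <- cfg$crosslink_lr_sd * sqrt(1 - rho^2)
    }
  } else {
    slope <- cfg$crosslink_ratio_slope
    noise_sd <- cfg$crosslink_noise_sd
    if (is.null(slope) || is.null(noise_sd)) {
      stop("set crosslink_target_cor or both slope and noise_sd")
    }
  }
  lr <- slope * s_c + rnorm(n, 0, noise_sd)
  junb_sig <- cfg$signal_baseline * 2^(lr / 2)
  tead_sig <- cfg$signal_baseline * 2^(-lr / 2)
  crosslink <- data.frame(peak_id = peaks$peak_id, ap1_score = ap1_score,
                          junb_signal = junb_sig, tead_signal = tead_sig,
                          true_log_ratio = lr, stringsAsFactors = FALSE)
  factor_peaks$JUNB$score <- junb_sig
  factor_peaks$TEAD$score <- tead_sig

  # YAP signal track: symmetric Gaussian bump at each YAP summit, so
  # summit calling recovers the jittered summit exactly
  amp <- rlnorm(n, log(cfg$signal_baseline), cfg$signal_lnorm_sd)
  factor_peaks$YAP$score <- amp
  factor_peaks$TAZ$score <- rlnorm(n, log(cfg$signal_baseline), cfg$signal_lnorm_sd)
  factor_peaks$STAT3$score <- rlnorm(n, log(cfg$signal_baseline), cfg$signal_lnorm_sd)
  tracks <- lapply(chroms, function(ch) {
    v <- numeric(L)
    idx <- which(peaks$chrom == ch)
    for (i in idx) {
      sm <- factor_peaks$YAP$summit[i] # rows align with `peaks`
      span <- max(0L, sm - 150L):min(L - 1L, sm + 150L)
      v[span + 1L] <- v[span + 1L] +
        round(amp[i] * exp(-(span - sm)^2 / (2 * cfg$signal_bump_sd^2)))
    }
    signal_track(ch, 0L, v)
  })
  names(tracks) <- chroms

  # YAP/TAZ replicate counts with planted paralog-specific sites
  mu <- rlnorm(n, log(cfg$nb_mean) - cfg$count_lnorm_sd^2 / 2,
               cfg$count_lnorm_sd)
  spec <- sample.int(n, cfg$n_specific_yap + cfg$n_specific_taz)
  yap_spec <- spec[seq_len(cfg$n_specific_yap)]
  taz_spec <- setdiff(spec, yap_spec)
  shift <- 2^(cfg$specific_log2fc / 2)
  mu_yap <- mu; mu_taz <- mu
  mu_yap[yap_spec] <- mu[yap_spec] * shift
  mu_taz[yap_spec] <- mu[yap_spec] / shift
  mu_yap[taz_spec] <- mu[taz_spec] / shift
  mu_taz[taz_spec] <- mu[taz_spec] * shift
  size <- 1 / cfg$nb_dispersion
  draw <- function(m) {
    matrix(rnbinom(n * cfg$n_replicates, mu = rep(m, cfg$n_replicates),
                   size = size),
           nrow = n, dimnames = list(peaks$peak_id,
                                     sprintf("rep%d", seq_len(cfg$n_replicates))))
  }
  counts <- list(YAP = draw(mu_yap), TAZ = draw(mu_taz))
  specific_truth <- rep("shared", n)
  specific_truth[yap_spec] <- "YAP_specific"
  specific_truth[taz_spec] <- "TAZ_specific"

  # knockout signals: a paralog-specific site loses binding only in the
  # matching knockout line
  ln_noise <- function() rlnorm(n, 0, cfg$ko_noise_sd)
  parent <- rlnorm(n, log(cfg$signal_baseline), cfg$signal_lnorm_sd)
  drop_yap <- ifelse(specific_truth == "YAP_specific", 1 - cfg$ko_drop, 1)
  drop_taz <- ifelse(specific_truth == "TAZ_specific", 1 - cfg$ko_drop, 1)
  ko <- data.frame(peak_id = peaks$peak_id,
                   parent = parent * ln_noise(),
                   yap_ko = parent * drop_yap * ln_noise(),
                   taz_ko = parent * drop_taz * ln_noise(),
                   stringsAsFactors = FALSE)

  # DHS atlas: uniform base sites; peak-bound sites get high accessibility
  # Z, and each receives same-Z non-bound "sibling" sites so matched
  # sampling always finds alternatives of the same Z-score
  dw <- cfg$dhs_width
  base_chrom <- sample(chroms, cfg$n_dhs, replace = TRUE)
  base_start <- as.integer(floor(runif(cfg$n_dhs, 0, L - dw)))
  dhs <- data.frame(chrom = base_chrom, start = base_start,
                    end = base_start + dw, stringsAsFactors = FALSE)
  yt_union <- rbind(factor_peaks$YAP[, c("chrom", "start", "end")],
                    factor_peaks$TAZ[, c("chrom", "start", "end")])
  bound <- GenomicRanges::countOverlaps(intervals_to_granges(dhs),
                                        intervals_to_granges(yt_union)) > 0
  z <- numeric(cfg$n_dhs)
  z[bound] <- rtnorm(sum(bound), cfg$bound_z_mean, cfg$bound_z_sd,
                     cfg$bound_z_mean - 2.5 * cfg$bound_z_sd,
                     cfg$bound_z_mean + 2.5 * cfg$bound_z_sd)
  z[!bound] <- rtnorm(sum(!bound), 0, 1, -2.5, 2.5)
  dhs$zscore <- z
  n_sib <- sum(bound) * cfg$dhs_sibling_factor
  sib_chrom <- sample(chroms, n_sib, replace = TRUE)
  sib_start <- as.integer(floor(runif(n_sib, L - 50000L, L - 1000L - dw)))
  sibs <- data.frame(chrom = sib_chrom, start = sib_start,
                     end = sib_start + dw,
                     zscore = rep(z[bound], each = cfg$dhs_sibling_factor),
                     stringsAsFactors = FALSE)
  dhs <- rbind(dhs, sibs)
  dhs$name <- sprintf("dhs_%06d", seq_len(nrow(dhs)))
  dhs <- dhs[, c("chrom", "start", "end", "name", "zscore")]

  # TSS annotation: a fraction of peaks get a proximal gene; background
  # genes live in the peak-free tail of each chromosome
  has_gene <- runif(n) < cfg$gene_fraction
  tgt_idx <- which(has_gene)
  tgt_tss <- data.frame(
    gene_id = sprintf("G%05d", tgt_idx),
    chrom = peaks$chrom[tgt_idx],
    position = peaks$true_summit[tgt_idx] +
      as.integer(round(runif(length(tgt_idx), -1500, 1500))),
    strand = sample(c("+", "-"), length(tgt_idx), replace = TRUE),
    stringsAsFactors = FALSE)
  bg_tss <- data.frame(
    gene_id = sprintf("BG%04d", seq_len(cfg$n_background_genes)),
    chrom = sample(chroms, cfg$n_background_genes, replace = TRUE),
    position = as.integer(floor(runif(cfg$n_background_genes,
                                      L - 50000L, L - 1000L))),
    strand = sample(c("+", "-"), cfg$n_background_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  # a second TSS for ~10% of target genes (multi-TSS genes are common)
  extra <- tgt_tss[runif(nrow(tgt_tss)) < 0.1, , drop = FALSE]
  if (nrow(extra) > 0L) extra$position <- extra$position + 500L
  tss <- rbind(tgt_tss, extra, bg_tss)
  gene_peak <- data.frame(peak = tgt_idx, gene_id = sprintf("G%05d", tgt_idx),
                          stringsAsFactors = FALSE)

  # signature truth: genes whose peak carries the configured motif class
  sig_classes <- SIGNATURE_CLASS_MAP[[cfg$signature_mode]]
  sig_genes <- sort(gene_peak$gene_id[peaks$class[gene_peak$peak] %in% sig_classes])

  # expression: log-normal baselines, per-gene noise, and a patient latent
  # factor loading on the signature genes
  genes <- c(sort(tgt_tss$gene_id), bg_tss$gene_id)
  n_g <- length(genes)
  n_p <- cfg$n_patients
  base <- rlnorm(n_g, cfg$expression_mean_log, cfg$expression_sd_log)
  noise_sd <- runif(n_g, cfg$expression_noise_range[1L],
                    cfg$expression_noise_range[2L])
  expr <- base * exp(matrix(rnorm(n_g * n_p, 0, rep(noise_sd, n_p)),
                            nrow = n_g))
  dimnames(expr) <- list(genes, sprintf("P%04d", seq_len(n_p)))
  u <- rnorm(n_p)
  is_sig <- genes %in% sig_genes
  expr[is_sig, ] <- expr[is_sig, , drop = FALSE] *
    matrix(exp(cfg$signature_effect * u), nrow = sum(is_sig), ncol = n_p,
           byrow = TRUE)

  # survival: exponential baseline, hazard multiplied for high-GSS patients
  g_tab <- gss(expr, sig_genes)
  high <- g_tab$gss >= 0
  haz <- cfg$base_hazard * ifelse(high, cfg$hazard_ratio, 1)
  t_event <- rexp(n_p, haz)
  if (cfg$censoring_fraction > 0) {
    f <- cfg$censoring_fraction
    pi_high <- mean(high)
    cens_frac <- function(rc) {
      pi_high * rc / (cfg$base_hazard * cfg$hazard_ratio + rc) +
        (1 - pi_high) * rc / (cfg$base_hazard + rc) - f
    }
    rc <- uniroot(cens_frac, c(1e-9, 1e3))$root
    t_cens <- rexp(n_p, rc)
  } else {
    t_cens <- rep(Inf, n_p)
  }
  survival <- data.frame(patient = colnames(expr),
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)

  # differential gene list enriched in target genes
  is_target <- genes %in% gene_peak$gene_id
  p_diff <- ifelse(is_target, cfg$diff_gene_rate_target, cfg$diff_gene_rate_other)
  diff_genes <- genes[runif(n_g) < p_diff]

  truth <- list(
    peaks = data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
                       true_summit = peaks$true_summit, class = peaks$class,
                       specific = specific_truth, stringsAsFactors = FALSE),
    planted_motifs = planted,
    signature_genes = sig_genes,
    signature_mode = cfg$signature_mode,
    gss = g_tab,
    hazard_ratio = cfg$hazard_ratio,
    target_genes = gene_peak$gene_id)

  structure(list(config = cfg, genome = genome, peaks = peaks,
                 gene_peak = gene_peak, factor_peaks = factor_peaks,
                 tracks = tracks, counts = counts, ko = ko,
                 crosslink = crosslink, dhs = dhs, tss = tss,
                 expression = expr, survival = survival,
                 diff_genes = diff_genes, truth = truth),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d peaks on %d chromosomes, %d DHSs, %d genes x %d patients (seed %d)\n",
              nrow(x$peaks), length(x$genome), nrow(x$dhs),
              nrow(x$expression), ncol(x$expression), x$config$seed))
  invisible(x)
}

#' Extract summit-window sequences for a peak set
#'
#' @param ds A [generate_dataset()] result (or any list with a `genome`
#'   character vector).
#' @param peaks Interval data.frame with `summit`.
#' @param half_width Window half-width (default the dataset's).
#' @return Named character vector of window sequences.
#' @export
summit_window_sequences <- function(ds, peaks, half_width = NULL) {
  if (is.null(half_width)) half_width <- ds$config$peak_half_width
  s <- substring(ds$genome[peaks$chrom], peaks$summit - half_width + 1L,
                 peaks$summit + half_width + 1L)
  names(s) <- if (!is.null(peaks$name)) peaks$name else rownames(peaks)
  s
}

#' Tabular ground-truth report for a synthetic dataset
#'
#' @param ds A [generate_dataset()] result.
#' @return list of data.frames: `peaks` (class + specific flags),
#'   `planted_motifs`, `signature_genes`, and scalars (`hazard_ratio`).
#' @export
truth_report <- function(ds) {
  stopifnot(inherits(ds, "synth_dataset"))
  ds$truth
}

#' Write a synthetic dataset to standard file formats
#'
#' FASTA genome, narrowPeak per factor, bedGraph YAP signal, TSV count
#' matrices, DHS atlas, TSS annotation, expression and survival tables,
#' differential gene list, YAML config, and JSON + TSV ground truth.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c()
  fa <- Biostrings::DNAStringSet(ds$genome)
  Biostrings::writeXStringSet(fa, p("genome.fa"))
  files["genome"] <- p("genome.fa")
  for (f in names(ds$factor_peaks)) {
    fn <- p(sprintf("peaks_%s.narrowPeak", f))
    write_intervals(ds$factor_peaks[[f]], fn, dialect = "narrowPeak")
    files[paste0("peaks_", f)] <- fn
  }
  write_bedgraph(ds$tracks, p("signal_YAP.bedGraph"))
  files["signal_YAP"] <- p("signal_YAP.bedGraph")
  for (f in names(ds$counts)) {
    fn <- p(sprintf("counts_%s.tsv", f))
    write.table(ds$counts[[f]], fn, sep = "\t", quote = FALSE, col.names = NA)
    files[paste0("counts_", f)] <- fn
  }
  write.table(ds$ko, p("knockout_signal.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["knockout"] <- p("knockout_signal.tsv")
  write.table(ds$crosslink, p("crosslink_signal.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files["crosslink"] <- p("crosslink_signal.tsv")
  write_dhs(ds$dhs, p("dhs_atlas.bed"))
  files["dhs"] <- p("dhs_atlas.bed")
  write_tss(ds$tss, p("tss.tsv"))
  files["tss"] <- p("tss.tsv")
  write.table(ds$expression, p("expression.tsv"), sep = "\t", quote = FALSE,
              col.names = NA)
  files["expression"] <- p("expression.tsv")
  write.table(ds$survival, p("survival.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["survival"] <- p("survival.tsv")
  writeLines(ds$diff_genes, p("diff_genes.txt"))
  files["diff_genes"] <- p("diff_genes.txt")
  cfg <- ds$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, p("config.yaml"))
  files["config"] <- p("config.yaml")
  tr <- truth_report(ds)
  write.table(tr$peaks, p("truth_peaks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["truth_peaks"] <- p("truth_peaks.tsv")
  write.table(tr$planted_motifs, p("truth_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files["truth_motifs"] <- p("truth_motifs.tsv")
  jsonlite::write_json(list(signature_mode = tr$signature_mode,
                            signature_genes = tr$signature_genes,
                            hazard_ratio = tr$hazard_ratio,
                            target_genes = tr$target_genes),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  files["truth_json"] <- p("truth.json")
  invisible(files)
}
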