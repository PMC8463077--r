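# Multi-factor co-occupancy: summit distances, overlap fractions,
# paralog-specific site calling and crosslink-ratio correlation.

#' Summit-distance summary between two peak sets
#'
#' For each peak in `a` whose interval intersects a peak in `b`, records the
#' distance to the nearest intersecting `b` summit (default). With
#' `restrict_to_overlap = FALSE` the nearest `b` summit on the same
#' chromosome is used irrespective of interval overlap.
#'
#' @param a,b Interval data.frames with `summit` columns.
#' @param restrict_to_overlap Only consider intersecting peak pairs
#'   (default `TRUE`).
#' @param pair Optional character pair of factor names for labeling.
#' @return Object of class `summit_distance_summary`: list with `pair`,
#'   `distances` (bp, one per matched `a` peak), `median`, `n`.
#' @export
summit_distance_summary <- function(a, b, restrict_to_overlap = TRUE,
                                    pair = c("A", "B")) {
  stopifnot(all(c("summit") %in% names(a)), all(c("summit") %in% names(b)))
  if (restrict_to_overlap) {
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(intervals_to_granges(a),
                                  intervals_to_granges(b)))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (length(qh) == 0L) {
      warning("no intersecting peak pairs between ", pair[1L], " and ", pair[2L])
      return(structure(list(pair = pair, distances = numeric(0),
                            median = NA_real_, n = 0L),
                       class = "summit_distance_summary"))
    }
    d <- abs(a$summit[qh] - b$summit[sh])
    dist <- as.numeric(tapply(d, qh, min))
  } else {
    dist <- rep(NA_real_, nrow(a))
    for (ch in unique(a$chrom)) {
      ai <- which(a$chrom == ch)
      bs <- sort(b$summit[b$chrom == ch])
      if (length(bs) == 0L) next
      i <- findInterval(a$summit[ai], bs)
      d_lo <- ifelse(i >= 1L, a$summit[ai] - bs[pmax(i, 1L)], Inf)
      d_hi <- ifelse(i < length(bs), bs[pmin(i + 1L, length(bs))] - a$summit[ai], Inf)
      dist[ai] <- pmin(d_lo, d_hi)
    }
    dist <- dist[is.finite(dist)]
  }
  structure(list(pair = pair, distances = dist, median = median(dist),
                 n = length(dist)),
            class = "summit_distance_summary")
}

#' @export
print.summit_distance_summary <- function(x, ...) {
  cat(sprintf("summit distances %s vs %s: n = %d, median = %s bp\n",
              x$pair[1L], x$pair[2L], x$n, format(x$median)))
  invisible(x)
}

#' Fraction of peaks in one set intersecting another
#'
#' Intersection means at least 1 bp of overlap between the half-open
#' intervals.
#'
#' @param a,b Interval data.frames.
#' @return Fraction of `a` peaks intersecting at least one `b` peak.
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L) stop("overlap fraction undefined for an empty peak set")
  if (nrow(b) == 0L) return(0)
  mean(suppressWarnings(
    GenomicRanges::countOverlaps(intervals_to_granges(a),
                                 intervals_to_granges(b))) > 0)
}

# Median-of-ratios size factors (reference = per-peak geometric mean across
# samples with all-positive counts).
size_factors_median_ratio <- function(counts) {
  pos <- rowSums(counts == 0) == 0L
  if (!any(pos)) stop("no peak has positive counts in every sample")
  lg <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2L, function(cc) exp(median(log(cc) - lg)))
}

#' Paralog-specific site calling from replicate counts
#'
#' Negative-binomial Wald test of per-peak binding difference between two
#' factors (e.g. YAP vs TAZ ChIP replicates) over a shared peak universe.
#' Counts are normalized with median-of-ratios size factors; a per-peak
#' method-of-moments dispersion is estimated from the pooled within-factor
#' variance (floored at `1e-8`) and shared across the two factors; the Wald
#' statistic tests the log2 fold change, with Benjamini-Hochberg adjustment
#' across peaks. Calls: `YAP_specific` when log2FC > 0 and padj < `alpha`,
#' `TAZ_specific` when log2FC < 0 and padj < `alpha`, otherwise `shared`
#' (names follow the `labels` argument).
#'
#' @param counts_a,counts_b Integer matrices, peaks x replicates (>= 2
#'   replicates each), same row order.
#' @param size_factors Optional numeric vector of length
#'   `ncol(counts_a) + ncol(counts_b)`; computed when `NULL`.
#' @param alpha Adjusted p-value cutoff for a specific call (default 0.05).
#' @param labels Call labels for (a-specific, b-specific, shared).
#' @return data.frame with `peak_id`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `pvalue`, `padj`, `call`.
#' @export
differential_binding <- function(counts_a, counts_b, size_factors = NULL,
                                 alpha = 0.05,
                                 labels = c("YAP_specific", "TAZ_specific", "shared")) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  stopifnot(nrow(counts_a) == nrow(counts_b), ncol(counts_a) >= 2L,
            ncol(counts_b) >= 2L)
  all_counts <- cbind(counts_a, counts_b)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(all_counts)
  stopifnot(length(size_factors) == ncol(all_counts), all(size_factors > 0))
  na <- ncol(counts_a)
  nb <- ncol(counts_b)
  norm <- sweep(all_counts, 2L, size_factors, "/")
  xa <- norm[, seq_len(na), drop = FALSE]
  xb <- norm[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  # pooled within-factor variance, then method-of-moments dispersion
  va <- apply(xa, 1L, var)
  vb <- apply(xb, 1L, var)
  v_pool <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  m_pool <- (na * ma + nb * mb) / (na + nb)
  disp <- pmax((v_pool - m_pool) / m_pool^2, 1e-8)
  eps <- 0.5 # half-count pseudo-mean to keep zero-mean fold changes finite
  lfc <- log2((ma + eps) / (mb + eps))
  se2 <- ((1 / (ma + eps) + disp) / na + (1 / (mb + eps) + disp) / nb) / log(2)^2
  z <- lfc / sqrt(se2)
  pvalue <- 2 * pnorm(-abs(z))
  zero <- ma + mb == 0
  pvalue[zero] <- 1
  lfc[zero] <- 0
  padj <- p.adjust(pvalue, method = "BH")
  call <- rep(labels[3L], length(lfc))
  call[lfc > 0 & padj < alpha] <- labels[1L]
  call[lfc < 0 & padj < alpha] <- labels[2L]
  ids <- rownames(counts_a)
  if (is.null(ids)) ids <- sprintf("peak_%05d", seq_along(lfc))
  data.frame(peak_id = ids, mean_a = ma, mean_b = mb, log2_fold_change = lfc,
             pvalue = pvalue, padj = padj,
             call = factor(call, levels = labels), stringsAsFactors = FALSE)
}

#' Confirm paralog-specific sites with knockout signal
#'
#' A candidate YAP-specific site is confirmed when its ChIP signal drops
#' below `drop_fraction` of the parental signal in the YAP-knockout line
#' while staying at or above that fraction in the TAZ-knockout line
#' (mirrored for TAZ-specific candidates). Sites with zero parental signal
#' are unconfirmed.
#'
#' @param call Factor/character vector of differential-binding calls
#'   (`YAP_specific` / `TAZ_specific` / `shared`).
#' @param parent,yap_ko,taz_ko Non-negative per-peak signal in the parental,
#'   YAP-knockout and TAZ-knockout lines.
#' @param drop_fraction Fraction of parental signal below which binding
#'   counts as lost (default 0.5).
#' @param peak_id Optional peak identifiers.
#' @return data.frame with the signals and a `confirmed` factor
#'   (`YAP_specific` / `TAZ_specific` / `unconfirmed`).
#' @export
confirm_specific_sites <- function(call, parent, yap_ko, taz_ko,
                                   drop_fraction = 0.5, peak_id = NULL) {
  stopifnot(drop_fraction > 0, drop_fraction < 1,
            length(parent) == length(call), length(yap_ko) == length(call),
            length(taz_ko) == length(call))
  thr <- drop_fraction * parent
  ok <- parent > 0
  conf <- rep("unconfirmed", length(call))
  conf[ok & call == "YAP_specific" & yap_ko < thr & taz_ko >= thr] <- "YAP_specific"
  conf[ok & call == "TAZ_specific" & taz_ko < thr & yap_ko >= thr] <- "TAZ_specific"
  if (is.null(peak_id)) peak_id <- sprintf("peak_%05d", seq_along(call))
  data.frame(peak_id = peak_id, call = as.character(call),
             signal_parent = parent, signal_yap_ko = yap_ko,
             signal_taz_ko = taz_ko,
             confirmed = factor(conf, levels = c("YAP_specific", "TAZ_specific",
                                                 "unconfirmed")),
             stringsAsFactors = FALSE)
}

#' Correlation of a two-factor crosslinking ratio with motif score
#'
#' Per peak, the crosslinking ratio is `log2((s1 + eps) / (s2 + eps))`
#' (e.g. JUNB vs TEAD ChIP signal); its Pearson correlation with the best
#' raw motif score distinguishes independent recruitment (signed
#' correlation) from a monolithic complex (no correlation).
#'
#' @param signal1,signal2 Non-negative per-peak signals.
#' @param motif_scores Per-peak best raw motif scores (`NA` excluded).
#' @param eps Pseudo-signal added before the log (default 1).
#' @return list with `log_ratio`, `r` (Pearson), `n`, and `zero_variance`
#'   (`TRUE` when either variable is constant, in which case `r` is 0).
#' @export
crosslink_ratio_correlation <- function(signal1, signal2, motif_scores, eps = 1) {
  stopifnot(length(signal1) == length(signal2),
            length(signal1) == length(motif_scores))
  lr <- log2((signal1 + eps) / (signal2 + eps))
  ok <- !is.na(motif_scores) & is.finite(lr)
  if (sum(ok) < 3L) stop("need >= 3 peaks with defined scores and ratios")
  zero_var <- sd(lr[ok]) == 0 || sd(motif_scores[ok]) == 0
  r <- if (zero_var) 0 else cor(lr[ok], motif_scores[ok])
  list(log_ratio = lr, r = r, n = sum(ok), zero_variance = zero_var)
}
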