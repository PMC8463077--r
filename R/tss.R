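# TSS-proximity annotation of peaks.
#
# The peak-to-TSS distance is 0 when the TSS lies inside the peak interval
# (end coordinate included), otherwise the gap to the nearer edge:
# max(start - tss, tss - end, 0). "Within w bp" is inclusive.

# Minimum distance from each peak to any TSS position, per the metric above.
peak_tss_distance <- function(peaks, tss) {
  d <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    pos <- sort(tss$position[tss$chrom == ch])
    if (length(pos) == 0L) next
    s <- peaks$start[pi]
    e <- peaks$end[pi]
    left <- findInterval(s, pos)              # rightmost TSS <= start
    d_left <- ifelse(left >= 1L, s - pos[pmax(left, 1L)], Inf)
    nxt <- left + 1L                          # leftmost TSS > start
    nxt_pos <- ifelse(nxt <= length(pos), pos[pmin(nxt, length(pos))], Inf)
    d_right <- ifelse(nxt_pos <= e, 0, nxt_pos - e)
    d[pi] <- pmin(d_left, d_right)
  }
  d
}

#' Label peaks as TSS-proximal or distal
#'
#' A peak is proximal when some TSS lies within `window_bp` of it
#' (inclusive); all other peaks are distal.
#'
#' @param peaks Interval data.frame.
#' @param tss TSS annotation data.frame (see [read_tss()]).
#' @param window_bp Proximity window in bp (default 2000).
#' @return Character vector (`"proximal"`/`"distal"`), one entry per peak.
#' @export
classify_tss_proximity <- function(peaks, tss, window_bp = 2000) {
  stopifnot(is.numeric(window_bp), window_bp > 0)
  if (nrow(tss) == 0L) {
    warning("empty TSS annotation: all peaks labeled distal")
    return(rep("distal", nrow(peaks)))
  }
  ifelse(peak_tss_distance(peaks, tss) <= window_bp, "proximal", "distal")
}

#' Fraction of peak summits just upstream of a TSS
#'
#' Counts peaks whose summit lies within `upstream_bp` upstream of at least
#' one TSS, strand-aware: upstream of a `+` TSS is the lower-coordinate side
#' (summit in `[tss - upstream_bp, tss]`), mirrored for `-`.
#'
#' @param peaks Interval data.frame with a `summit` column.
#' @param tss TSS annotation data.frame.
#' @param upstream_bp Upstream window in bp (default 150).
#' @return A single fraction in \[0, 1\].
#' @export
upstream_window_fraction <- function(peaks, tss, upstream_bp = 150) {
  stopifnot(is.numeric(upstream_bp), upstream_bp > 0)
  if (!"summit" %in% names(peaks)) stop("peaks need a summit column")
  if (nrow(peaks) == 0L) return(0)
  hit <- logical(nrow(peaks))
  count_in <- function(pos, lo, hi) {
    # number of sorted positions in [lo, hi]
    findInterval(hi, pos) - findInterval(lo - 0.5, pos)
  }
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    sm <- peaks$summit[pi]
    plus <- sort(tss$position[tss$chrom == ch & tss$strand == "+"])
    minus <- sort(tss$position[tss$chrom == ch & tss$strand == "-"])
    n_hit <- numeric(length(pi))
    if (length(plus) > 0L) {
      # + strand: need a TSS in [summit, summit + upstream_bp]
      n_hit <- n_hit + count_in(plus, sm, sm + upstream_bp)
    }
    if (length(minus) > 0L) {
      # - strand: need a TSS in [summit - upstream_bp, summit]
      n_hit <- n_hit + count_in(minus, sm - upstream_bp, sm)
    }
    hit[pi] <- n_hit > 0
  }
  mean(hit)
}
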