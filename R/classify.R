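# Motif-class assignment of peaks and positional analyses of hits.

MOTIF_CLASSES <- c("AP1_only", "TEAD_only", "STAT3_only", "AP1_TEAD",
                   "AP1_STAT3", "TEAD_STAT3", "AP1_TEAD_STAT3", "none")

# Logical per-peak "has >= 1 passing hit for any of these motifs".
has_any_hit <- function(profiles, motif_names) {
  motif_names <- intersect(motif_names, profiles$motifs)
  if (length(motif_names) == 0L) return(rep(FALSE, length(profiles$peak_id)))
  unname(rowSums(profiles$n_hits[, motif_names, drop = FALSE] > 0) > 0)
}

#' Monomer-or-dimer TEAD motif call
#'
#' A peak counts as having a TEAD motif when either the TEAD monomer or the
#' TEAD dimer motif has at least one hit at the scanning threshold.
#'
#' @param profiles A [scan_peaks()] result.
#' @param monomer,dimer Motif names of the TEAD monomer and dimer PWMs.
#' @return Logical vector, one entry per peak.
#' @export
has_tead_motif <- function(profiles, monomer = "TEAD", dimer = "TEAD_DIMER") {
  has_any_hit(profiles, c(monomer, dimer))
}

#' Assign each peak a motif-class label
#'
#' The label is the subset of \{AP-1, TEAD, STAT3\} with at least one
#' passing hit in the summit window; TEAD uses the monomer-or-dimer rule of
#' [has_tead_motif()]. Peaks with no hit for any of the three are `none`.
#'
#' @param profiles A [scan_peaks()] result.
#' @param ap1,stat3 Motif names for AP-1 and STAT3.
#' @param tead Character vector of TEAD motif names (monomer and dimer).
#' @return Factor with levels `AP1_only`, `TEAD_only`, `STAT3_only`,
#'   `AP1_TEAD`, `AP1_STAT3`, `TEAD_STAT3`, `AP1_TEAD_STAT3`, `none`.
#' @export
classify_peaks <- function(profiles, ap1 = "AP1", tead = c("TEAD", "TEAD_DIMER"),
                           stat3 = "STAT3") {
  a <- has_any_hit(profiles, ap1)
  t_ <- has_any_hit(profiles, tead)
  s <- has_any_hit(profiles, stat3)
  lab <- rep("none", length(a))
  lab[a & !t_ & !s] <- "AP1_only"
  lab[!a & t_ & !s] <- "TEAD_only"
  lab[!a & !t_ & s] <- "STAT3_only"
  lab[a & t_ & !s] <- "AP1_TEAD"
  lab[a & !t_ & s] <- "AP1_STAT3"
  lab[!a & t_ & s] <- "TEAD_STAT3"
  lab[a & t_ & s] <- "AP1_TEAD_STAT3"
  factor(lab, levels = MOTIF_CLASSES)
}

#' Histogram of motif positions around peak summits
#'
#' Each hit contributes once at its motif-window center offset relative to
#' the peak summit; bins tile `[-window_bp, +window_bp]`.
#'
#' @param profiles A [scan_peaks()] result (scan windows should extend at
#'   least `window_bp` either side of the summit).
#' @param motif Motif name, or a character vector to pool several motifs.
#' @param window_bp Half-width of the histogram range (default 500).
#' @param bin_bp Bin width (default 10). If it does not divide
#'   `2 * window_bp` the last bin is truncated, with a warning.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
positional_histogram <- function(profiles, motif, window_bp = 500, bin_bp = 10) {
  stopifnot(window_bp > 0, bin_bp > 0)
  motif <- intersect(motif, profiles$motifs)
  off <- unlist(lapply(profiles$hits[motif], function(h) h$center_offset),
                use.names = FALSE)
  breaks <- seq(-window_bp, window_bp, by = bin_bp)
  if (utils::tail(breaks, 1L) < window_bp) {
    warning("bin_bp does not divide 2*window_bp; last bin truncated")
    breaks <- c(breaks, window_bp)
  }
  if (length(off) == 0L) {
    counts <- integer(length(breaks) - 1L)
  } else {
    off <- off[off >= -window_bp & off <= window_bp]
    counts <- as.integer(table(cut(off, breaks, include.lowest = TRUE,
                                   right = FALSE)))
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             count = counts)
}

#' Signed spacing between AP-1 and TEAD motifs at composite peaks
#'
#' For every peak carrying at least one passing AP-1 hit and one passing
#' TEAD hit, returns the minimum-magnitude center-to-center distance with
#' sign `TEAD center - AP-1 center`. Ties in magnitude break to the smaller
#' signed value. Peaks lacking either motif are skipped.
#'
#' @param profiles A [scan_peaks()] result.
#' @param ap1 AP-1 motif name.
#' @param tead Character vector of TEAD motif names.
#' @return Named numeric vector of signed distances (bp), one per composite
#'   peak.
#' @export
composite_spacing <- function(profiles, ap1 = "AP1", tead = c("TEAD", "TEAD_DIMER")) {
  tead <- intersect(tead, profiles$motifs)
  ha <- profiles$hits[[ap1]]
  ht <- do.call(rbind, profiles$hits[tead])
  both <- intersect(unique(ha$peak), unique(ht$peak))
  out <- vapply(both, function(pk) {
    d <- outer(ht$center_offset[ht$peak == pk], ha$center_offset[ha$peak == pk], "-")
    d <- as.numeric(d)
    d[order(abs(d), d)][1L]
  }, numeric(1))
  names(out) <- profiles$peak_id[both]
  out
}

#' Export motif hits as BED6
#'
#' Converts window-relative hit positions to absolute coordinates using the
#' scanned peak windows and writes one BED6 line per hit, with the score
#' column carrying the log2 score in bits.
#'
#' @param profiles A [scan_peaks()] result.
#' @param windows Interval data.frame of the scanned windows, in the same
#'   order as the profiles' peaks.
#' @param motif Motif name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_hits_bed <- function(profiles, windows, motif, path) {
  h <- profiles$hits[[motif]]
  if (is.null(h)) stop("no such motif: ", motif)
  starts <- windows$start[h$peak] + h$position
  # motif width from the stored geometry: center = position + (width-1)/2
  wdt <- as.integer(round(2 * (h$center_offset + profiles$summit_offset - h$position) + 1))
  out <- data.frame(windows$chrom[h$peak], starts, starts + wdt,
                    paste0(motif, "_", seq_len(nrow(h))),
                    formatC(h$score, format = "f", digits = 3), h$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
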