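# PWM scanning of sequences and summit windows.

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else (N) -> NA.
encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], BASES)
}

# Per-window scores of a score matrix over an encoded sequence, one strand.
# Windows containing NA (N) score NA. Returns both the continuous score
# (bits, for reporting) and the discretized integer score (units of
# `step_bits`, for threshold decisions shared with the exact-p-value DP).
window_scores <- function(score_matrix, code, step_bits = 1e-3) {
  W <- nrow(score_matrix)
  n_win <- length(code) - W + 1L
  if (n_win < 1L) return(list(cont = numeric(0), int = numeric(0)))
  S <- round(score_matrix / step_bits)
  sc <- numeric(n_win)
  si <- numeric(n_win)
  for (j in seq_len(W)) {
    idx <- code[j:(j + n_win - 1L)]
    sc <- sc + score_matrix[j, ][idx]
    si <- si + S[j, ][idx]
  }
  list(cont = sc, int = si)
}

# Convert a continuous threshold (possibly carrying a step_bits attribute
# from score_threshold_from_pvalue) into integer discretization units.
threshold_units <- function(threshold, step_bits) {
  if (is.infinite(threshold)) return(threshold)
  st <- attr(threshold, "step_bits")
  if (!is.null(st) && abs(st - step_bits) > 1e-12) {
    stop("threshold was computed at step_bits = ", st,
         " but scanning uses ", step_bits)
  }
  ceiling(as.numeric(threshold) / step_bits - 1e-9)
}

#' Scan a sequence for PWM matches on both strands
#'
#' Every window of the motif width is scored on both strands as the sum of
#' `log2(p_reg(base) / background(base))`; windows containing `N` are
#' skipped. Reverse-strand hits are reported with the plus-strand start
#' coordinate of the window.
#'
#' @param x A [pwm()].
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param threshold Score threshold in bits (e.g. from
#'   [score_threshold_from_pvalue()]); use `-Inf` to report every window.
#'   The hit decision is made on scores discretized at `step_bits`, the
#'   same discretization the exact p-value computation uses.
#' @param step_bits Score discretization step (default `1e-3`, matching
#'   [score_threshold_from_pvalue()]).
#' @return data.frame with columns `position` (0-based window start),
#'   `strand` (`+`/`-`), `score` (bits), ordered by position.
#' @export
scan_sequence <- function(x, sequence, threshold, step_bits = 1e-3) {
  stopifnot(inherits(x, "pwm"))
  code <- encode_dna(sequence)
  if (length(code) < x$width) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  tu <- threshold_units(threshold, step_bits)
  rc <- reverse_complement_pwm(x)
  fwd <- window_scores(x$score, code, step_bits)
  rev_ <- window_scores(rc$score, code, step_bits)
  fi <- which(!is.na(fwd$int) & fwd$int >= tu)
  ri <- which(!is.na(rev_$int) & rev_$int >= tu)
  out <- data.frame(
    position = c(fi, ri) - 1L,
    strand = c(rep("+", length(fi)), rep("-", length(ri))),
    score = c(fwd$cont[fi], rev_$cont[ri]),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Scan summit windows of many peaks with a set of PWMs
#'
#' Scans each peak's summit-window sequence with every motif at its exact
#' p-value threshold and collects, per peak and motif: all passing hits, the
#' hit count, and the best raw window score regardless of threshold (used by
#' crosslink-ratio correlation analyses).
#'
#' Sequences are concatenated with `N` spacers so each motif is scanned in a
#' single vectorized pass.
#'
#' @param seqs Character vector (or `Biostrings::DNAStringSet`) of window
#'   sequences, one per peak, all the same length; names become peak ids.
#' @param pwms Named list of [pwm()] objects.
#' @param pvalue Match p-value used to derive each motif's threshold
#'   (default `1e-4`).
#' @param thresholds Optional named numeric vector of score thresholds that
#'   overrides the p-value derivation.
#' @param summit_offset 0-based position of the summit within each window;
#'   defaults to the window center. Hit `center_offset`s are relative to it.
#' @param step_bits Score discretization step shared with the threshold
#'   computation (default `1e-3`).
#' @return An object of class `peak_motif_profiles`: list with `peak_id`,
#'   `motifs`, `thresholds`, `best_raw` (peak x motif matrix), `n_hits`
#'   (peak x motif matrix), and `hits` (per motif, a data.frame with
#'   `peak_id`, `position`, `strand`, `score`, `center_offset`).
#' @export
scan_peaks <- function(seqs, pwms, pvalue = 1e-4, thresholds = NULL,
                       summit_offset = NULL, step_bits = 1e-3) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs), length(seqs) > 0L, is.list(pwms),
            !is.null(names(pwms)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("all window sequences must have equal length")
  n <- length(seqs)
  peak_id <- if (is.null(names(seqs))) sprintf("peak_%05d", seq_len(n)) else names(seqs)
  if (is.null(summit_offset)) summit_offset <- (L - 1L) / 2
  maxW <- max(vapply(pwms, function(p) p$width, integer(1)))
  B <- L + maxW # block stride: sequence plus N spacer
  concat <- paste0(paste0(seqs, strrep("N", maxW)), collapse = "")
  code <- encode_dna(concat)
  motifs <- names(pwms)
  best_raw <- matrix(NA_real_, n, length(motifs), dimnames = list(peak_id, motifs))
  n_hits <- matrix(0L, n, length(motifs), dimnames = list(peak_id, motifs))
  hits <- setNames(vector("list", length(motifs)), motifs)
  thr_out <- setNames(numeric(length(motifs)), motifs)
  for (m in motifs) {
    x <- pwms[[m]]
    thr <- if (!is.null(thresholds) && m %in% names(thresholds)) {
      thresholds[[m]]
    } else {
      score_threshold_from_pvalue(x, pvalue, step_bits)
    }
    thr_out[m] <- as.numeric(thr)
    tu <- threshold_units(thr, step_bits)
    rc <- reverse_complement_pwm(x)
    fwd <- window_scores(x$score, code, step_bits)
    rev_ <- window_scores(rc$score, code, step_bits)
    pad <- n * B - length(fwd$cont)
    fwd_m <- matrix(c(fwd$cont, rep(NA_real_, pad)), nrow = B)
    rev_m <- matrix(c(rev_$cont, rep(NA_real_, pad)), nrow = B)
    comb <- pmax(fwd_m, rev_m, na.rm = TRUE)
    best_raw[, m] <- suppressWarnings(apply(comb, 2L, max, na.rm = TRUE))
    best_raw[!is.finite(best_raw[, m]), m] <- NA_real_
    collect <- function(ws, strand) {
      i <- which(!is.na(ws$int) & ws$int >= tu)
      if (length(i) == 0L) return(NULL)
      pk <- (i - 1L) %/% B + 1L
      pos <- (i - 1L) %% B
      data.frame(peak_id = peak_id[pk], peak = pk, position = pos,
                 strand = strand, score = ws$cont[i], stringsAsFactors = FALSE)
    }
    h <- rbind(collect(fwd, "+"), collect(rev_, "-"))
    if (is.null(h)) {
      h <- data.frame(peak_id = character(), peak = integer(),
                      position = integer(), strand = character(),
                      score = numeric(), center_offset = numeric(),
                      stringsAsFactors = FALSE)
    } else {
      h$center_offset <- h$position + (x$width - 1) / 2 - summit_offset
      h <- h[order(h$peak, h$position, h$strand), , drop = FALSE]
      tab <- tabulate(h$peak, nbins = n)
      n_hits[, m] <- tab
    }
    rownames(h) <- NULL
    hits[[m]] <- h
  }
  structure(list(peak_id = peak_id, motifs = motifs, thresholds = thr_out,
                 pvalue = pvalue, best_raw = best_raw, n_hits = n_hits,
                 hits = hits, window_length = L, summit_offset = summit_offset),
            class = "peak_motif_profiles")
}

#' @export
print.peak_motif_profiles <- function(x, ...) {
  cat(sprintf("peak_motif_profiles: %d peaks x %d motifs (%s)\n",
              length(x$peak_id), length(x$motifs),
              paste(x$motifs, collapse = ", ")))
  invisible(x)
}
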