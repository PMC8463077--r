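# Per-base signal tracks: construction, bedGraph I/O, Gaussian smoothing and
# summit calling.

#' Construct a per-base signal track
#'
#' @param chrom Chromosome name.
#' @param origin 0-based start coordinate of the first value.
#' @param values Numeric vector of per-base, non-negative signal.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(chrom, origin, values) {
  stopifnot(length(chrom) == 1L, nzchar(chrom), origin >= 0)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty signal track")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("signal values must be finite and >= 0")
  }
  structure(list(chrom = chrom, origin = as.integer(origin), values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track %s:[%d,%d) (%d bp, max %.3g)\n", x$chrom,
              x$origin, x$origin + length(x$values), length(x$values),
              max(x$values)))
  invisible(x)
}

#' Read a bedGraph file into per-chromosome signal tracks
#'
#' Each chromosome becomes one dense [signal_track()] spanning from its first
#' to its last covered base; uncovered gaps are filled with zeros.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return Named list of `signal_track` objects, one per chromosome.
#' @export
read_bedgraph <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stop("bedGraph needs 4 columns")
  names(x)[1:4] <- c("chrom", "start", "end", "value")
  lapply(split(x, x$chrom), function(d) {
    origin <- min(d$start)
    len <- max(d$end) - origin
    v <- numeric(len)
    for (i in seq_len(nrow(d))) {
      v[(d$start[i] - origin + 1L):(d$end[i] - origin)] <- d$value[i]
    }
    signal_track(d$chrom[1L], origin, v)
  })
}

#' Write signal tracks as bedGraph
#'
#' Runs of equal value are collapsed to single lines; zero runs are omitted.
#'
#' @param tracks A `signal_track` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "signal_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    r <- rle(tr$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", tr$chrom, tr$origin + starts[keep],
                         tr$origin + ends[keep],
                         formatC(r$values[keep], format = "g", digits = 8)), con)
    }
  }
  invisible(path)
}

#' Smooth a signal track with a Gaussian kernel
#'
#' Discrete Gaussian convolution with kernel standard deviation
#' `bandwidth_bp`, truncated at `truncate_sd` standard deviations and
#' renormalized to unit sum, so total signal mass is conserved away from the
#' track edges. The output has the same length and origin as the input;
#' positions beyond the edges are treated as zero signal.
#'
#' @param track A [signal_track()].
#' @param bandwidth_bp Kernel standard deviation in base pairs (default 10).
#' @param truncate_sd Truncation half-width in standard deviations (default 4).
#' @return A smoothed `signal_track`.
#' @export
smooth_signal <- function(track, bandwidth_bp = 10, truncate_sd = 4) {
  stopifnot(inherits(track, "signal_track"))
  if (!is.numeric(bandwidth_bp) || bandwidth_bp <= 0) {
    stop("bandwidth_bp must be > 0")
  }
  v <- track$values
  r <- ceiling(truncate_sd * bandwidth_bp)
  k <- dnorm(seq(-r, r), sd = bandwidth_bp)
  k <- k / sum(k)
  padded <- c(numeric(r), v, numeric(r))
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  sm <- as.numeric(sm)[(r + 1L):(r + length(v))]
  sm[sm < 0] <- 0 # guard against tiny negative round-off
  signal_track(track$chrom, track$origin, sm)
}

#' Call the summit of each peak from a signal track
#'
#' The summit is the position of maximum (optionally smoothed) signal within
#' the peak interval; ties break to the smallest coordinate. Peaks whose
#' signal is identically zero keep their start coordinate as summit, with a
#' warning.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`).
#' @param tracks Named list of [signal_track()] objects (names =
#'   chromosomes), or a single track.
#' @param smooth_bandwidth_bp If non-`NULL`, tracks are smoothed with
#'   [smooth_signal()] at this bandwidth before the argmax (default 10).
#' @return The input data.frame with a `summit` column added/overwritten.
#' @export
find_summits <- function(intervals, tracks, smooth_bandwidth_bp = 10) {
  if (inherits(tracks, "signal_track")) {
    tracks <- setNames(list(tracks), tracks$chrom)
  }
  if (!is.null(smooth_bandwidth_bp)) {
    tracks <- lapply(tracks, smooth_signal, bandwidth_bp = smooth_bandwidth_bp)
  }
  n_zero <- 0L
  summit <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    tr <- tracks[[intervals$chrom[i]]]
    if (is.null(tr)) stop("no signal track for chromosome ", intervals$chrom[i])
    s <- intervals$start[i]
    e <- intervals$end[i]
    if (s < tr$origin || e > tr$origin + length(tr$values)) {
      stop("peak ", intervals$chrom[i], ":[", s, ",", e,
           ") outside track coverage [", tr$origin, ",",
           tr$origin + length(tr$values), ")")
    }
    w <- tr$values[(s - tr$origin + 1L):(e - tr$origin)]
    if (max(w) == 0) {
      n_zero <- n_zero + 1L
      summit[i] <- s
    } else {
      summit[i] <- s + which.max(w) - 1L
    }
  }
  if (n_zero > 0L) {
    warning(n_zero, " peak(s) had all-zero signal; summit set to peak start")
  }
  intervals$summit <- summit
  intervals
}

#' Replace peak intervals by fixed-width summit windows
#'
#' Each peak becomes the interval `[summit - half_width, summit + half_width + 1)`
#' (length `2 * half_width + 1`, inclusive of both ends), clipped at
#' coordinate 0. This removes the bias of peak-length differences between
#' transcription factors.
#'
#' @param peaks Interval data.frame with a `summit` column.
#' @param half_width Window half-width in bp (default 150).
#' @return The data.frame with `start`/`end` replaced by the summit window.
#' @export
adjust_to_summit_window <- function(peaks, half_width = 150) {
  stopifnot(is.numeric(half_width), half_width > 0)
  if (!"summit" %in% names(peaks) || any(is.na(peaks$summit))) {
    stop("adjust_to_summit_window needs a complete summit column")
  }
  half_width <- as.integer(half_width)
  peaks$start <- pmax(0L, peaks$summit - half_width)
  peaks$end <- peaks$summit + half_width + 1L
  peaks
}
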