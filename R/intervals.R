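# Interval I/O and the internal interval representation.
#
# Intervals live in plain data.frames with columns chrom, start, end and
# optionally name, score, summit. Coordinates are 0-based half-open (BED);
# `summit` is an absolute base position with interval.start <= summit < end.

#' Read genomic intervals from BED or narrowPeak text
#'
#' Parses tab-separated interval files into the package's 0-based half-open
#' data.frame representation. For narrowPeak input the 10th column (summit
#' offset relative to `start`) is converted to an absolute `summit`
#' coordinate; an offset of -1 means "no summit recorded" and yields `NA`.
#'
#' @param path Path to a tab-separated BED3/BED4/BED6 or narrowPeak file.
#' @param dialect `"auto"` (default) infers narrowPeak from a 10-column
#'   layout, otherwise `"bed"` or `"narrowPeak"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit` (the last three `NA` where absent).
#' @export
read_intervals <- function(path, dialect = c("auto", "bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), summit = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (dialect == "auto") dialect <- if (all(nf == 10L)) "narrowPeak" else "bed"
  min_cols <- if (dialect == "narrowPeak") 10L else 3L
  bad <- which(nf < min_cols)
  if (length(bad) > 0L) {
    stop("malformed ", dialect, " line ", bad[1L], " in ", path,
         ": expected >= ", min_cols, " fields, found ", nf[bad[1L]])
  }
  get_col <- function(i) vapply(fields, function(f) f[[i]], character(1))
  chrom <- get_col(1L)
  start <- suppressWarnings(as.integer(get_col(2L)))
  end <- suppressWarnings(as.integer(get_col(3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad) > 0L) stop("malformed coordinates at line ", bad[1L], " in ", path)
  bad <- which(end <= start | start < 0L)
  if (length(bad) > 0L) {
    stop("invalid interval at line ", bad[1L], " in ", path,
         ": need 0 <= start < end, got [", start[bad[1L]], ", ", end[bad[1L]], ")")
  }
  name <- if (all(nf >= 4L)) get_col(4L) else NA_character_
  score <- if (all(nf >= 5L)) suppressWarnings(as.numeric(get_col(5L))) else NA_real_
  summit <- NA_integer_
  if (dialect == "narrowPeak") {
    offset <- suppressWarnings(as.integer(get_col(10L)))
    summit <- ifelse(!is.na(offset) & offset >= 0L, start + offset, NA_integer_)
    # column 7 (signalValue) is the meaningful score; column 5 is display-only
    score <- suppressWarnings(as.numeric(get_col(7L)))
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, summit = as.integer(summit), stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED or narrowPeak
#'
#' Inverse of [read_intervals()]: coordinates round-trip exactly.
#'
#' @param x Interval data.frame (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `summit`).
#' @param path Output path.
#' @param dialect `"bed"` writes BED6 when name/score are present (BED3
#'   otherwise); `"narrowPeak"` writes the 10-column format with the summit
#'   offset in column 10 (-1 when missing).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  nm <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else rep(".", nrow(x))
  sc <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else rep(0, nrow(x))
  if (dialect == "bed") {
    out <- if ("name" %in% names(x) || "score" %in% names(x)) {
      data.frame(x$chrom, x$start, x$end, nm, sc, ".")
    } else data.frame(x$chrom, x$start, x$end)
  } else {
    off <- if ("summit" %in% names(x)) ifelse(is.na(x$summit), -1L, x$summit - x$start) else rep(-1L, nrow(x))
    out <- data.frame(x$chrom, x$start, x$end, nm, 0L, ".", sc, -1, -1, off)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of an interval data.frame (1-based closed, as GenomicRanges
# expects). Internal: all public surfaces stay 0-based half-open.
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Read a DHS atlas with accessibility Z-scores
#'
#' Expects BED-like tab-separated text whose 5th column carries the
#' DNase-seq accessibility Z-score (4th column is a site name).
#'
#' @param path Path to the atlas file.
#' @return Interval data.frame with an extra numeric `zscore` column.
#' @export
read_dhs <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 5L) stop("DHS atlas needs >= 5 columns (chrom, start, end, name, zscore)")
  out <- data.frame(chrom = x[[1L]], start = as.integer(x[[2L]]),
                    end = as.integer(x[[3L]]), name = as.character(x[[4L]]),
                    zscore = as.numeric(x[[5L]]), stringsAsFactors = FALSE)
  if (any(!is.finite(out$zscore))) stop("non-finite Z-score in ", path)
  out
}

#' Write a DHS atlas (BED4 + Z-score column)
#' @param x DHS data.frame (`chrom`, `start`, `end`, `name`, `zscore`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dhs <- function(x, path) {
  write.table(data.frame(x$chrom, x$start, x$end, x$name,
                         formatC(x$zscore, format = "g", digits = 8)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' A 4-column tab-separated table: gene_id, chrom, position (0-based),
#' strand (`+`/`-`). A gene may appear on several rows (multiple TSSs).
#'
#' @param path Path to the annotation.
#' @return data.frame with columns `gene_id`, `chrom`, `position`, `strand`.
#' @export
read_tss <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stop("TSS annotation needs 4 columns (gene_id, chrom, position, strand)")
  out <- data.frame(gene_id = as.character(x[[1L]]), chrom = as.character(x[[2L]]),
                    position = as.integer(x[[3L]]), strand = as.character(x[[4L]]),
                    stringsAsFactors = FALSE)
  if (any(out$position < 0L)) stop("negative TSS position in ", path)
  if (!all(out$strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  out
}

#' Write a TSS annotation table
#' @param x TSS data.frame as returned by [read_tss()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(x, path) {
  write.table(x[, c("gene_id", "chrom", "position", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
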