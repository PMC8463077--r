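# Position weight matrices and exact p-value score thresholds.
#
# A PWM is scored as the log2 likelihood ratio of the motif model against a
# 0-order background. The null score distribution of a single window is
# computed exactly by dynamic programming over discretized scores, which
# turns a match p-value into a score threshold (the strategy FIMO uses).

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Base probabilities are regularized with a pseudocount before scoring:
#' `p_reg = (p + pseudocount * background) / (1 + pseudocount)`, so rows sum
#' to 1 and no log score is infinite.
#'
#' @param name Motif identifier.
#' @param probs W x 4 matrix of base probabilities (columns A, C, G, T);
#'   rows of counts are normalized to probabilities.
#' @param background Length-4 background probability vector (default uniform).
#' @param pseudocount Small positive regularizer (default 0.01).
#' @return An object of class `pwm` with a `score` matrix in log2 units.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stop("PWM width must be >= 1")
  if (any(probs < 0)) stop("negative entries in probs")
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6,
            all(background > 0), pseudocount >= 0)
  rs <- rowSums(probs)
  if (any(rs == 0) && pseudocount == 0) {
    stop("PWM '", name, "' has an all-zero row and pseudocount 0; ",
         "set a positive pseudocount")
  }
  probs <- probs / ifelse(rs == 0, 1, rs)
  reg <- sweep(probs, 2L, background * pseudocount, "+") / (1 + pseudocount)
  reg <- reg / rowSums(reg)
  colnames(reg) <- BASES
  # zero regularized probabilities (pseudocount 0) get a -100-bit floor so
  # scores stay finite; such windows can never reach a sane threshold
  score <- pmax(log2(sweep(reg, 2L, background, "/")), -100)
  structure(list(name = name, probs = probs, probs_reg = reg,
                 background = background, pseudocount = pseudocount,
                 score = score, width = nrow(reg)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' width %d, max score %.2f bits\n", x$name, x$width,
              sum(apply(x$score, 1L, max))))
  invisible(x)
}

#' Reverse complement of a PWM
#' @param x A [pwm()].
#' @return The reverse-complement `pwm` (rows reversed, A<->T, C<->G).
#' @export
reverse_complement_pwm <- function(x) {
  rc <- x$probs[rev(seq_len(x$width)), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(rc) <- BASES
  pwm(x$name, rc, background = x$background[c(4L, 3L, 2L, 1L)],
      pseudocount = x$pseudocount)
}

#' Read JASPAR-format motif matrices
#'
#' Parses the standard JASPAR text layout (`>id name` header followed by
#' four `A [ .. ]` ... `T [ .. ]` rows of counts or probabilities).
#'
#' @param path Path to a JASPAR-format file (may hold several motifs).
#' @param background,pseudocount Passed to [pwm()].
#' @return A named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' headers in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    header <- sub("^>\\s*", "", lines[from])
    name <- strsplit(header, "\\s+")[[1L]][1L]
    block <- lines[(from + 1L):to]
    rows <- lapply(BASES, function(b) {
      ln <- grep(paste0("^", b, "\\b"), block, value = TRUE)
      if (length(ln) != 1L) stop("motif '", name, "': missing row for base ", b)
      as.numeric(strsplit(trimws(gsub("^[ACGT]\\s*\\[?|\\]\\s*$", "", ln)),
                          "\\s+")[[1L]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("motif '", name, "': ragged rows")
    m <- t(do.call(rbind, rows)) # W x 4
    out[[name]] <- pwm(name, m, background = background, pseudocount = pseudocount)
  }
  out
}

# Column score matrix rounded to integer units of `step_bits`.
discretize_scores <- function(x, step_bits) {
  round(x$score / step_bits)
}

# Exact null distribution of the discretized single-window score under the
# 0-order background, by column-wise convolution. Returns list(lo, probs)
# where probs[k] = P(sum == lo + k - 1).
pwm_null_distribution <- function(x, step_bits = 1e-3) {
  S <- discretize_scores(x, step_bits)
  lo <- sum(apply(S, 1L, min))
  hi <- sum(apply(S, 1L, max))
  if (hi - lo > 5e7) stop("score range too wide; increase step_bits")
  probs <- 1
  cur_lo <- 0L
  for (j in seq_len(x$width)) {
    row <- S[j, ]
    rlo <- min(row)
    new <- numeric(length(probs) + (max(row) - rlo))
    for (b in 1:4) {
      sh <- row[b] - rlo
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs * x$background[b]
    }
    probs <- new
    cur_lo <- cur_lo + rlo
  }
  stopifnot(cur_lo == lo)
  list(lo = lo, probs = probs, step_bits = step_bits)
}

#' Score threshold attaining a match p-value
#'
#' Computes the exact null distribution of the single-window log-likelihood
#' score under the PWM's 0-order background (dynamic programming over scores
#' discretized at `step_bits`) and returns the smallest achievable score `s`
#' with `P(score >= s) <= p`. Scanning at this threshold therefore admits
#' exactly the null tail of mass `pvalue_attained` (the largest achievable
#' tail not exceeding `p`).
#'
#' @param x A [pwm()].
#' @param p Target match p-value in (0, 1); default `1e-4`.
#' @param step_bits Score discretization step in bits (default `1e-3`).
#' @return The threshold in bits, with attributes `pvalue_attained` (the
#'   exact null tail probability at the threshold) and `step_bits`.
#' @export
score_threshold_from_pvalue <- function(x, p = 1e-4, step_bits = 1e-3) {
  stopifnot(inherits(x, "pwm"), is.numeric(p), p > 0, p < 1)
  d <- pwm_null_distribution(x, step_bits)
  tails <- rev(cumsum(rev(d$probs)))
  ok <- which(d$probs > 0 & tails <= p)
  if (length(ok) == 0L) {
    # even the maximal achievable score is too frequent: nothing can pass
    thr <- (d$lo + length(d$probs)) * step_bits
    attained <- 0
  } else {
    thr <- (d$lo + ok[1L] - 1L) * step_bits
    attained <- tails[ok[1L]]
  }
  structure(thr, pvalue_attained = attained, step_bits = step_bits)
}
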