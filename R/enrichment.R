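# Accessibility-matched control sets and chi-square enrichment analyses.

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample an accessibility-matched control set of DHSs
#'
#' Builds a control set with the same accessibility Z-score distribution as
#' the bound DHS set: Z-scores are binned at `bin_width`, the bound set's
#' per-bin counts are drawn without replacement from the candidate atlas,
#' and any sampled site intersecting the exclusion intervals (the target
#' peaks) is iteratively replaced by an unused candidate from the same bin
#' until none intersects. Deterministic given `seed`.
#'
#' @param bound DHS data.frame (`chrom`, `start`, `end`, `zscore`) of sites
#'   intersecting the target peaks.
#' @param candidates DHS data.frame to sample from (the full atlas).
#' @param exclusion Interval data.frame of target peaks that the control set
#'   must not intersect.
#' @param seed Integer RNG seed.
#' @param bin_width Z-score bin width for matching (default 0.1).
#' @return Object of class `control_set`: list with `records` (rows of
#'   `candidates`), `seed`, `bin_width`, `bin_counts`.
#' @export
sample_matched_controls <- function(bound, candidates, exclusion, seed,
                                    bin_width = 0.1) {
  stopifnot(bin_width > 0, nrow(bound) > 0L, nrow(candidates) > 0L)
  bin_of <- function(z) floor(z / bin_width)
  b_bin <- bin_of(bound$zscore)
  c_bin <- bin_of(candidates$zscore)
  excluded <- if (nrow(exclusion) > 0L) {
    GenomicRanges::countOverlaps(intervals_to_granges(candidates),
                                 intervals_to_granges(exclusion)) > 0
  } else rep(FALSE, nrow(candidates))
  need <- table(b_bin)
  picked <- integer(0)
  with_seed(seed, {
    for (bn in names(need)) {
      k <- as.integer(need[[bn]])
      pool <- which(c_bin == as.numeric(bn))
      n_clean <- sum(!excluded[pool])
      if (n_clean < k) {
        stop("Z-score bin [", as.numeric(bn) * bin_width, ", ",
             (as.numeric(bn) + 1) * bin_width, "): need ", k,
             " non-excluded candidates, have ", n_clean,
             " (shortfall ", k - n_clean, ")")
      }
      sel <- pool[sample.int(length(pool), k)]
      unused <- setdiff(pool, sel)
      repeat {
        bad <- which(excluded[sel])
        if (length(bad) == 0L) break
        repl_pool <- unused[!excluded[unused]]
        repl <- repl_pool[sample.int(length(repl_pool), length(bad))]
        unused <- setdiff(unused, repl)
        sel[bad] <- repl
      }
      picked <- c(picked, sel)
    }
  })
  records <- candidates[picked, , drop = FALSE]
  rownames(records) <- NULL
  # hard assertion: the control set never intersects the exclusion intervals
  if (nrow(exclusion) > 0L) {
    stopifnot(all(GenomicRanges::countOverlaps(
      intervals_to_granges(records), intervals_to_granges(exclusion)) == 0))
  }
  structure(list(records = records, seed = seed, bin_width = bin_width,
                 bin_counts = need),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("control_set: %d DHSs matched over %d Z-bins (width %.3g, seed %d)\n",
              nrow(x$records), length(x$bin_counts), x$bin_width, x$seed))
  invisible(x)
}

# Pearson chi-square (df = 1) on a 2x2 table given as four counts, closed
# form N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); optional Yates correction.
chisq_2x2 <- function(a, b, c_, d, correct = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- if (denom == 0) 0 else n * num^2 / denom
  list(statistic = stat, pvalue = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Coerce a profiles object or logical vector to "has motif" logicals.
as_has_motif <- function(x, motif) {
  if (is.logical(x)) return(x)
  if (inherits(x, "peak_motif_profiles")) return(has_any_hit(x, motif))
  stop("expected a logical vector or peak_motif_profiles object")
}

#' Motif enrichment in target peaks versus matched controls
#'
#' Chi-square test (df = 1, no continuity correction by default) on the 2x2
#' has-motif / lacks-motif by target / control table, with the fold change
#' of motif frequencies.
#'
#' @param target,control Logical has-motif vectors, or [scan_peaks()]
#'   results (scanned with identical PWMs and thresholds).
#' @param motif Motif name(s) when profiles are supplied; several names are
#'   combined with the any-hit rule (e.g. TEAD monomer + dimer).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return Object of class `enrichment_result`: list with `motif`,
#'   `frac_target`, `frac_control`, `fold` (`Inf` flagged when the control
#'   frequency is 0), `chisq`, `pvalue`, counts.
#' @export
motif_enrichment <- function(target, control, motif = NULL, correct = FALSE) {
  t_has <- as_has_motif(target, motif)
  c_has <- as_has_motif(control, motif)
  if (length(t_has) == 0L || length(c_has) == 0L) stop("empty peak set")
  a <- sum(t_has); b <- sum(!t_has); c_ <- sum(c_has); d <- sum(!c_has)
  ft <- a / (a + b)
  fc <- c_ / (c_ + d)
  cs <- chisq_2x2(a, b, c_, d, correct = correct)
  structure(list(motif = if (is.null(motif)) NA_character_ else paste(motif, collapse = "+"),
                 frac_target = ft, frac_control = fc,
                 fold = if (fc == 0) Inf else ft / fc,
                 infinite_fold = fc == 0 && ft > 0,
                 n_target = a + b, n_control = c_ + d,
                 chisq = cs$statistic, pvalue = cs$pvalue),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: %.3f vs %.3f (fold %.2f), chisq = %.2f, p = %.3g\n",
              x$motif, x$frac_target, x$frac_control, x$fold, x$chisq, x$pvalue))
  invisible(x)
}

#' Pairwise motif co-occurrence enrichment
#'
#' Fold-enrichment of peaks carrying both motifs of a pair in targets
#' relative to matched controls.
#'
#' @param target,control [scan_peaks()] results or a 2-column logical
#'   matrix (one column per motif).
#' @param pair Character vector of two motif names (each element may itself
#'   be a vector-valued name group when profiles are supplied, e.g.
#'   `list(c("TEAD","TEAD_DIMER"), "AP1")`).
#' @return Object of class `cooccurrence_result`: list with `pair`,
#'   `frac_target`, `frac_control`, `fold` (`Inf` flagged when the control
#'   pair frequency is 0), `chisq`, `pvalue`.
#' @export
pairwise_cooccurrence <- function(target, control, pair) {
  if (!is.list(pair)) pair <- as.list(pair)
  stopifnot(length(pair) == 2L)
  both <- function(x) as_has_motif(x, pair[[1L]]) & as_has_motif(x, pair[[2L]])
  t_both <- both(target)
  c_both <- both(control)
  ft <- mean(t_both)
  fc <- mean(c_both)
  cs <- chisq_2x2(sum(t_both), sum(!t_both), sum(c_both), sum(!c_both))
  structure(list(pair = vapply(pair, paste, character(1), collapse = "+"),
                 frac_target = ft, frac_control = fc,
                 fold = if (fc == 0) Inf else ft / fc,
                 infinite_fold = fc == 0 && ft > 0,
                 chisq = cs$statistic, pvalue = cs$pvalue),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf("%s & %s: %.3f vs %.3f (fold %s)\n", x$pair[1L], x$pair[2L],
              x$frac_target, x$frac_control, format(x$fold)))
  invisible(x)
}

#' Assign genes as targets of a peak set
#'
#' A gene is a target when any of its TSSs lies within `window_bp` of any
#' peak (edge distance, inclusive; 0 when the TSS is inside a peak).
#'
#' @param peaks Interval data.frame.
#' @param tss TSS annotation data.frame (see [read_tss()]).
#' @param window_bp Proximity window (default 2000).
#' @return Named logical vector over all genes in the annotation.
#' @export
assign_target_genes <- function(peaks, tss, window_bp = 2000) {
  stopifnot(window_bp > 0)
  genes <- unique(tss$gene_id)
  if (nrow(peaks) == 0L) return(setNames(rep(FALSE, length(genes)), genes))
  # distance from each TSS point to the nearest peak, with the same edge
  # metric as classify_tss_proximity
  d <- rep(Inf, nrow(tss))
  for (ch in unique(tss$chrom)) {
    ti <- which(tss$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0L) next
    ord <- order(pk$start)
    ps <- pk$start[ord]
    pe_max <- cummax(pk$end[ord]) # rightmost end among peaks starting <= pos
    pos <- tss$position[ti]
    i <- findInterval(pos, ps)
    d_left <- ifelse(i >= 1L, pmax(pos - pe_max[pmax(i, 1L)], 0), Inf)
    d_next <- ifelse(i < length(ps), ps[pmin(i + 1L, length(ps))] - pos, Inf)
    d[ti] <- pmin(d_left, d_next)
  }
  hit <- d <= window_bp
  tgt <- tapply(hit, tss$gene_id, any)
  setNames(as.logical(tgt[genes]), genes)
}

#' Target-gene enrichment of a differential gene set
#'
#' Compares the fraction of factor-target genes among differential genes
#' against a same-size control set of genes sampled uniformly without
#' replacement from the annotation, with a chi-square test on the 2x2
#' target/non-target by differential/control table.
#'
#' @param diff_genes Character vector of differential gene ids.
#' @param all_genes Character vector of all annotated genes to sample
#'   controls from (`length >= 2 * length(diff_genes)`).
#' @param target_map Named logical vector from [assign_target_genes()].
#' @param seed Integer RNG seed for the control draw.
#' @return Object of class `target_gene_enrichment`: counts of the 2x2
#'   table, `chisq`, `pvalue`, and the control gene set.
#' @export
target_gene_enrichment <- function(diff_genes, all_genes, target_map, seed) {
  if (length(diff_genes) == 0L) stop("empty differential gene set")
  if (length(all_genes) < 2L * length(diff_genes)) {
    stop("need at least twice as many annotated genes as differential genes")
  }
  ctrl <- with_seed(seed, sample(all_genes, length(diff_genes)))
  is_t <- function(g) {
    v <- target_map[g]
    v[is.na(v)] <- FALSE
    v
  }
  dt <- sum(is_t(diff_genes)); dn <- length(diff_genes) - dt
  ct <- sum(is_t(ctrl)); cn <- length(ctrl) - ct
  cs <- chisq_2x2(dt, dn, ct, cn)
  structure(list(n_diff_target = dt, n_diff_nontarget = dn,
                 n_ctrl_target = ct, n_ctrl_nontarget = cn,
                 chisq = cs$statistic, pvalue = cs$pvalue,
                 control_genes = ctrl, seed = seed),
            class = "target_gene_enrichment")
}

#' @export
print.target_gene_enrichment <- function(x, ...) {
  cat(sprintf("target genes: %d/%d differential vs %d/%d control, chisq = %.2f, p = %.3g\n",
              x$n_diff_target, x$n_diff_target + x$n_diff_nontarget,
              x$n_ctrl_target, x$n_ctrl_target + x$n_ctrl_nontarget,
              x$chisq, x$pvalue))
  invisible(x)
}
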