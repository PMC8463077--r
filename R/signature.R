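# Motif-class gene signatures and the gene signature score (GSS).

#' Define a motif-class gene signature
#'
#' Starting from genes targeted by shared YAP/TAZ peaks, keeps the genes
#' with at least one proximal peak of the requested motif composition:
#' `"AP1_only"` = an AP-1 motif but no TEAD motif, `"TEAD_only"` = a TEAD
#' motif but no AP-1 motif, `"AP1_and_TEAD"` = both. STAT3 status does not
#' enter the rule, so e.g. `AP1_STAT3`-class peaks qualify for
#' `"AP1_only"`. Genes with several proximal peaks may belong to several
#' signatures.
#'
#' @param peak_classes Factor/character of motif-class labels per peak
#'   (from [classify_peaks()]).
#' @param peak_genes data.frame linking peaks to proximal genes, with
#'   columns `peak` (index or id matching `names(peak_classes)` order) and
#'   `gene_id`.
#' @param mode One of `"AP1_only"`, `"TEAD_only"`, `"AP1_and_TEAD"`.
#' @param name Optional signature name (defaults to the mode).
#' @return Object of class `gene_signature`: list with `name`, `genes`,
#'   `definition`.
#' @export
define_motif_signature <- function(peak_classes, peak_genes,
                                   mode = c("AP1_only", "TEAD_only", "AP1_and_TEAD"),
                                   name = NULL) {
  mode <- match.arg(mode)
  qualifying <- switch(mode,
    AP1_only = c("AP1_only", "AP1_STAT3"),
    TEAD_only = c("TEAD_only", "TEAD_STAT3"),
    AP1_and_TEAD = c("AP1_TEAD", "AP1_TEAD_STAT3"))
  cls <- as.character(peak_classes)
  keep_peaks <- which(cls %in% qualifying)
  genes <- sort(unique(peak_genes$gene_id[peak_genes$peak %in% keep_peaks]))
  if (length(genes) == 0L) {
    stop("no genes qualify for mode '", mode,
         "'; generate a larger dataset or relax the proximity window")
  }
  structure(list(name = if (is.null(name)) mode else name, genes = genes,
                 definition = list(mode = mode, classes = qualifying,
                                   n_peaks = length(keep_peaks))),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes (classes %s)\n", x$name,
              length(x$genes), paste(x$definition$classes, collapse = ", ")))
  invisible(x)
}

#' Split a signature by motif-site count
#'
#' Divides a motif signature into sub-signatures of genes targeted by a
#' qualifying peak carrying exactly one passing motif site versus two or
#' more. A gene with several qualifying peaks may fall into both sets.
#'
#' @param signature A [define_motif_signature()] result.
#' @param profiles A [scan_peaks()] result (for per-peak hit counts).
#' @param peak_classes Motif-class labels per peak.
#' @param peak_genes Peak-to-gene links as in [define_motif_signature()].
#' @param motif Motif name(s) whose hit counts are summed (e.g. `"AP1"`).
#' @return list with `one_motif` and `multi_motif` gene vectors.
#' @export
split_by_motif_count <- function(signature, profiles, peak_classes, peak_genes,
                                 motif) {
  motif <- intersect(motif, profiles$motifs)
  counts <- rowSums(profiles$n_hits[, motif, drop = FALSE])
  qual <- as.character(peak_classes) %in% signature$definition$classes
  link <- peak_genes[peak_genes$gene_id %in% signature$genes, , drop = FALSE]
  link <- link[qual[link$peak], , drop = FALSE]
  n <- counts[link$peak]
  list(one_motif = sort(unique(link$gene_id[n == 1])),
       multi_motif = sort(unique(link$gene_id[n >= 2])))
}

#' Coefficient-of-variation filter on an expression matrix
#'
#' Removes genes with little (`CV < low`) or excessive (`CV > high`)
#' variation across patients; CV is the sample standard deviation divided
#' by the mean. Genes with zero mean are removed.
#'
#' @param expr Numeric matrix, genes x patients.
#' @param low,high CV bounds (defaults 0.05 and 0.85).
#' @return Character vector of retained gene names.
#' @export
cv_filter <- function(expr, low = 0.05, high = 0.85) {
  stopifnot(low < high)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("CV filter needs >= 2 patients")
  m <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  rownames(expr)[!is.na(cv) & cv >= low & cv <= high]
}

#' Gene signature score per patient
#'
#' `GSS_j = sum_i (x_ij - mu_i) / sigma_i` over the signature genes, where
#' `mu_i` and `sigma_i` (sample standard deviation) are computed across all
#' patients. Patients are stratified at 0: `high` when `GSS >= 0` (the
#' high-expression, high-risk group), `low` otherwise. By the cohort
#' z-score identity, GSS sums to zero over patients.
#'
#' @param expr Numeric matrix, genes x patients (no missing values).
#' @param signature A [define_motif_signature()] result or character vector
#'   of gene ids; genes must be rows of `expr`.
#' @param log2_transform Score `log2(x + 1)` instead of the raw scale
#'   (default `FALSE`).
#' @return data.frame with `patient`, `gss`, `group` (`low`/`high`).
#' @export
gss <- function(expr, signature, log2_transform = FALSE) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stop(length(missing), " signature gene(s) absent from the expression matrix",
         " (first: ", missing[1L], ")")
  }
  x <- expr[genes, , drop = FALSE]
  if (log2_transform) x <- log2(x + 1)
  mu <- rowMeans(x)
  sigma <- apply(x, 1L, sd)
  if (any(sigma == 0)) {
    stop("zero-variance signature gene(s); apply cv_filter() first")
  }
  z <- (x - mu) / sigma
  g <- colSums(z)
  data.frame(patient = colnames(expr), gss = g,
             group = factor(ifelse(g < 0, "low", "high"), levels = c("low", "high")),
             stringsAsFactors = FALSE, row.names = NULL)
}
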