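# Summit distances, overlap fractions, differential binding, knockout
# confirmation, crosslink-ratio correlation.

mk_peaks <- function(summits, hw = 150, chrom = "chr1") {
  data.frame(chrom = chrom, start = pmax(0L, summits - hw),
             end = summits + hw + 1L, summit = summits)
}

test_that("summit distances: identity, constant shift, and no-overlap warning", {
  a <- mk_peaks(seq(1000L, 50000L, 1000L))
  expect_equal(summit_distance_summary(a, a)$median, 0)
  b <- a
  b$summit <- b$summit + 40L
  expect_equal(summit_distance_summary(a, b)$median, 40)
  far <- mk_peaks(seq(1000L, 5000L, 1000L), chrom = "chr9")
  expect_warning(s <- summit_distance_summary(a, far), "no intersecting")
  expect_equal(s$n, 0L)
})

test_that("summit distances with per-factor jitter match the half-normal median", {
  set.seed(91)
  true <- seq(1000L, by = 1000L, length.out = 5000L)
  a <- mk_peaks(true + as.integer(round(rnorm(5000, 0, 15))))
  b <- mk_peaks(true + as.integer(round(rnorm(5000, 0, 15))))
  s <- summit_distance_summary(a, b)
  # median |N(0, 15*sqrt(2))| = qnorm(0.75) * 15 * sqrt(2) ~ 14.31
  expect_equal(s$median, qnorm(0.75) * 15 * sqrt(2), tolerance = 1.5 / 14.3)
})

test_that("overlap fraction counts intersecting peaks and is monotone in B", {
  a <- mk_peaks(seq(1000L, 10000L, 1000L)) # 10 peaks
  expect_equal(overlap_fraction(a, a), 1.0)
  b3 <- a[1:3, ]
  expect_equal(overlap_fraction(a, b3), 0.3)
  expect_equal(overlap_fraction(a, mk_peaks(5000L, chrom = "chr7")), 0.0)
  expect_error(overlap_fraction(a[0, ], a), "empty")
  set.seed(92)
  for (i in 1:5) {
    bs <- a[sample.int(10, 4), ]
    grown <- rbind(bs, a[sample.int(10, 2), ])
    expect_gte(overlap_fraction(a, grown), overlap_fraction(a, bs))
  }
})

test_that("differential binding is null on identical or rescaled counts", {
  set.seed(101)
  a <- matrix(rnbinom(300, mu = 150, size = 20), 100)
  db <- differential_binding(a, a)
  expect_true(all(db$log2_fold_change == 0))
  expect_true(all(db$call == "shared"))
  # doubling every library is absorbed by size-factor normalization
  db2 <- differential_binding(a, a * 2L)
  expect_equal(db2$log2_fold_change, rep(0, 100), tolerance = 1e-9)
  expect_true(all(db2$padj >= db2$pvalue))
})

test_that("differential binding recovers planted fold changes", {
  set.seed(102)
  n0 <- 2000; n1 <- 100
  null_a <- matrix(rnbinom(n0 * 3, mu = 200, size = 20), n0)
  null_b <- matrix(rnbinom(n0 * 3, mu = 200, size = 20), n0)
  up_a <- matrix(rnbinom(n1 * 3, mu = 200 * 2^1.5, size = 20), n1)
  up_b <- matrix(rnbinom(n1 * 3, mu = 200 * 2^-1.5, size = 20), n1)
  # type-I error on a pure null universe
  db0 <- differential_binding(null_a, null_b)
  expect_lte(mean(db0$padj < 0.05), 0.05)
  # sensitivity with planted sites in the mix
  db <- differential_binding(rbind(null_a, up_a), rbind(null_b, up_b))
  expect_gte(mean(db$call[(n0 + 1):(n0 + n1)] == "YAP_specific"), 0.9)
  # all-zero peaks are called shared with p = 1
  z <- differential_binding(rbind(null_a, 0), rbind(null_b, 0))
  expect_equal(z$pvalue[n0 + 1], 1)
  expect_equal(as.character(z$call[n0 + 1]), "shared")
})

test_that("fold-change estimates agree with DESeq2 on the same counts", {
  set.seed(103)
  n <- 300
  mu <- rep(c(200, 200 * 8), c(250, 50))
  a <- matrix(rnbinom(n * 3, mu = mu, size = 20), n)
  b <- matrix(rnbinom(n * 3, mu = 200, size = 20), n)
  db <- differential_binding(a, b)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = cbind(a, b),
      colData = data.frame(condition = factor(rep(c("A", "B"), each = 3),
                                              levels = c("B", "A"))),
      design = ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  ok <- !is.na(res$padj)
  expect_gt(cor(db$log2_fold_change[ok], res$log2FoldChange[ok]), 0.95)
  # planted peaks found significant by both routes
  planted <- 251:300
  expect_gte(mean(db$call[planted] == "YAP_specific"), 0.9)
  expect_gte(mean(res$padj[planted] < 0.05, na.rm = TRUE), 0.9)
})

test_that("knockout confirmation applies the drop rule and is antisymmetric", {
  call <- c("YAP_specific", "YAP_specific", "TAZ_specific", "shared", "YAP_specific")
  parent <- c(100, 100, 100, 100, 0)
  yko <- c(10, 10, 95, 95, 0)
  tko <- c(95, 10, 10, 95, 0)
  out <- confirm_specific_sites(call, parent, yko, tko)
  expect_equal(as.character(out$confirmed),
               c("YAP_specific", "unconfirmed", "TAZ_specific", "unconfirmed",
                 "unconfirmed"))
  # swapping KO columns and YAP/TAZ labels swaps confirmations exactly
  swap_call <- chartr("YT", "TY", sub("YAP", "yap", call))
  swap_call <- ifelse(call == "YAP_specific", "TAZ_specific",
                      ifelse(call == "TAZ_specific", "YAP_specific", call))
  sw <- confirm_specific_sites(swap_call, parent, tko, yko)
  map <- c(YAP_specific = "TAZ_specific", TAZ_specific = "YAP_specific",
           unconfirmed = "unconfirmed")
  expect_equal(as.character(sw$confirmed), unname(map[as.character(out$confirmed)]))
})

test_that("crosslink-ratio correlation handles degenerate and linear cases", {
  s <- runif(50, 10, 100)
  out <- crosslink_ratio_correlation(s, s, rnorm(50))
  expect_true(out$zero_variance)
  expect_equal(out$r, 0)

  score <- rnorm(100)
  lr <- 0.1 * score
  s1 <- 2^lr * 100 - 1
  s2 <- rep(99, 100)
  out2 <- crosslink_ratio_correlation(s1, s2, score, eps = 1)
  expect_equal(out2$r, 1.0, tolerance = 1e-9)
  expect_error(crosslink_ratio_correlation(1:2, 1:2, 1:2), ">= 3")
})

test_that("pearson r is scale-invariant only without pseudo-signal", {
  set.seed(111)
  score <- rnorm(500)
  s1 <- 50 * 2^(0.5 * score + rnorm(500, 0, 1))
  s2 <- 50 * 2^(-0.5 * score + rnorm(500, 0, 1))
  r0 <- crosslink_ratio_correlation(s1, s2, score, eps = 0)$r
  r0_scaled <- crosslink_ratio_correlation(10 * s1, 10 * s2, score, eps = 0)$r
  expect_equal(r0, r0_scaled, tolerance = 1e-12)
  r1 <- crosslink_ratio_correlation(s1, s2, score, eps = 1)$r
  r1_scaled <- crosslink_ratio_correlation(10 * s1, 10 * s2, score, eps = 1)$r
  expect_false(isTRUE(all.equal(r1, r1_scaled, tolerance = 1e-6)))
})
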