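# Interval I/O, smoothing, summit calling, summit windows, TSS proximity.

test_that("BED and narrowPeak parsing follows the format definitions", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t400\tpk1", "chr2\t0\t50\tpk2"), f)
  x <- read_intervals(f)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(100L, 0L))
  expect_equal(x$end, c(400L, 50L))
  expect_equal(x$name, c("pk1", "pk2"))

  np <- withr::local_tempfile()
  writeLines(c("chr1\t100\t400\tpk1\t0\t.\t5.5\t-1\t-1\t50",
               "chr1\t500\t700\tpk2\t0\t.\t2.0\t-1\t-1\t-1"), np)
  y <- read_intervals(np)
  expect_equal(y$summit, c(150L, NA_integer_))
  expect_equal(y$score, c(5.5, 2.0))
})

test_that("malformed interval lines error with their line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t400", "chr1\t400\t100"), f)
  expect_error(read_intervals(f), "line 2")
  f2 <- withr::local_tempfile()
  writeLines("chr1\t100", f2)
  expect_error(read_intervals(f2), "line 1")
})

test_that("interval write/read round-trips coordinates exactly", {
  set.seed(5)
  n <- 50
  start <- sample.int(1e6, n)
  x <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE), start = start,
                  end = start + sample.int(500, n),
                  name = sprintf("p%d", 1:n), score = runif(n),
                  summit = start + 5L)
  for (d in c("bed", "narrowPeak")) {
    f <- withr::local_tempfile()
    write_intervals(x, f, dialect = d)
    y <- read_intervals(f, dialect = d)
    expect_equal(y$start, x$start)
    expect_equal(y$end, x$end)
    expect_equal(y$chrom, x$chrom)
    if (d == "narrowPeak") expect_equal(y$summit, x$summit)
  }
})

test_that("Gaussian smoothing keeps constants, mass and symmetry", {
  tr <- signal_track("chr1", 0, rep(3, 200))
  sm <- smooth_signal(tr, 10)
  expect_equal(sm$values[60:140], rep(3, 81), tolerance = 1e-9)

  imp <- numeric(201)
  imp[101] <- 1
  sm2 <- smooth_signal(signal_track("chr1", 0, imp), 10)
  expect_equal(sum(sm2$values), 1, tolerance = 1e-9)       # unit-sum kernel
  expect_equal(which.max(sm2$values), 101L)                # symmetric kernel
  expect_length(sm2$values, 201L)

  # total mass conserved for signal away from edges
  set.seed(9)
  v <- numeric(400)
  v[150:250] <- runif(101, 0, 5)
  sm3 <- smooth_signal(signal_track("chr1", 0, v), 10)
  expect_equal(sum(sm3$values), sum(v), tolerance = 1e-6 * sum(v))
})

test_that("smoothing rejects empty tracks and bad bandwidths", {
  expect_error(signal_track("chr1", 0, numeric(0)), "empty")
  tr <- signal_track("chr1", 0, 1:5)
  expect_error(smooth_signal(tr, 0), "bandwidth")
})

test_that("summit calling takes the argmax with first-position tie-break", {
  tr <- signal_track("chr1", 10, c(0, 1, 3, 1, 0))
  pk <- data.frame(chrom = "chr1", start = 10L, end = 15L)
  expect_equal(find_summits(pk, tr, smooth_bandwidth_bp = NULL)$summit, 12L)

  tr2 <- signal_track("chr1", 10, c(2, 2))
  pk2 <- data.frame(chrom = "chr1", start = 10L, end = 12L)
  expect_equal(find_summits(pk2, tr2, smooth_bandwidth_bp = NULL)$summit, 10L)

  tr3 <- signal_track("chr1", 10, rep(0, 5))
  expect_warning(out <- find_summits(pk, tr3, smooth_bandwidth_bp = NULL),
                 "all-zero")
  expect_equal(out$summit, 10L)

  expect_error(find_summits(data.frame(chrom = "chr1", start = 5L, end = 20L),
                            tr, smooth_bandwidth_bp = NULL), "coverage")
})

test_that("summit windows have fixed width and clip at zero", {
  pk <- data.frame(chrom = "chr1", start = 0L, end = 2000L,
                   summit = c(1000L, 100L, 5L))
  w <- adjust_to_summit_window(pk, 150)
  expect_equal(w$start[1:2], c(850L, 0L))
  expect_equal(w$end[1:2], c(1151L, 251L))
  w2 <- adjust_to_summit_window(pk[3, ], 1)
  expect_equal(c(w2$start, w2$end), c(4L, 7L))
  # all unclipped windows have length 2*hw+1
  expect_true(all((w$end - w$start)[w$start > 0] == 301L))
})

test_that("TSS proximity uses inclusive edge distance", {
  pk <- data.frame(chrom = "chr1", start = 1000L, end = 1300L)
  tss1 <- data.frame(gene_id = "g", chrom = "chr1", position = 1100L, strand = "+")
  expect_equal(classify_tss_proximity(pk, tss1), "proximal") # contained
  tss2 <- data.frame(gene_id = "g", chrom = "chr1", position = 3300L, strand = "+")
  expect_equal(classify_tss_proximity(pk, tss2, 2000), "proximal") # gap 2000
  tss3 <- data.frame(gene_id = "g", chrom = "chr1", position = 3301L, strand = "+")
  expect_equal(classify_tss_proximity(pk, tss3, 2000), "distal") # gap 2001
  expect_warning(out <- classify_tss_proximity(pk, tss1[0, ]), "empty")
  expect_equal(out, "distal")
})

test_that("proximity labels are invariant to TSS order", {
  set.seed(11)
  pk <- data.frame(chrom = "chr1", start = seq(0, 90000, 10000),
                   end = seq(300, 90300, 10000))
  tss <- data.frame(gene_id = sprintf("g%d", 1:30), chrom = "chr1",
                    position = sample.int(1e5, 30), strand = "+")
  a <- classify_tss_proximity(pk, tss)
  b <- classify_tss_proximity(pk, tss[sample.int(30), ])
  expect_identical(a, b)
})

test_that("upstream-window fraction is strand-aware", {
  pk <- function(s) data.frame(chrom = "chr1", start = s - 10L, end = s + 10L,
                               summit = s)
  plus <- data.frame(gene_id = "g", chrom = "chr1", position = 1000L, strand = "+")
  minus <- data.frame(gene_id = "g", chrom = "chr1", position = 1000L, strand = "-")
  expect_equal(upstream_window_fraction(pk(950L), plus, 150), 1)  # 50 bp upstream
  expect_equal(upstream_window_fraction(pk(1050L), plus, 150), 0) # downstream
  expect_equal(upstream_window_fraction(pk(1050L), minus, 150), 1) # mirrored
})

test_that("bedGraph round-trips through signal tracks", {
  tr <- signal_track("chr3", 100, c(0, 0, 5, 5, 2, 0, 7))
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)[["chr3"]]
  # zero-valued leading bases are dropped on write; covered span matches
  expect_equal(back$origin, 102L)
  expect_equal(back$values, c(5, 5, 2, 0, 7))
})
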