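# PWM thresholds, scanning, classification, positional analyses.

test_that("width-1 threshold is enumerable by hand", {
  p1 <- pwm("w1", matrix(c(1, 0, 0, 0), 1, 4), pseudocount = 0)
  thr <- score_threshold_from_pvalue(p1, 0.25)
  expect_equal(as.numeric(thr), 2)              # log2(1/0.25): only "A" passes
  expect_equal(attr(thr, "pvalue_attained"), 0.25)
})

test_that("degenerate PWM without pseudocount is rejected", {
  expect_error(pwm("bad", matrix(c(0, 0, 0, 0, 1, 0, 0, 0), 2, 4, byrow = TRUE),
                   pseudocount = 0), "pseudocount")
})

test_that("a near-1 p-value pushes the threshold to the bottom of the score support", {
  set.seed(21)
  x <- random_pwm(4)
  thr <- score_threshold_from_pvalue(x, 1 - 1e-6)
  # everything except (at most) the minimal-score windows passes
  sq <- random_dna(5000)
  h <- scan_sequence(x, sq, thr)
  expect_gt(nrow(h) / (2 * (5000 - 3)), 0.95)
})

test_that("DP threshold equals exhaustive enumeration on random PWMs", {
  set.seed(31)
  for (i in 1:5) {
    x <- random_pwm(sample(3:6, 1))
    for (p in c(1e-2, 1e-3)) {
      thr <- score_threshold_from_pvalue(x, p)
      oracle <- enum_threshold_units(x, p)
      expect_equal(round(as.numeric(thr) / 1e-3), oracle$units)
      expect_equal(attr(thr, "pvalue_attained"), oracle$tail, tolerance = 1e-12)
    }
  }
})

test_that("width-3 threshold with p = 1/64 selects exactly the best window", {
  set.seed(32)
  repeat { # need distinct column maxima so the top window is unique
    x <- random_pwm(3)
    if (all(apply(x$probs, 1L, function(r) sum(r == max(r))) == 1L)) break
  }
  thr <- score_threshold_from_pvalue(x, 1 / 64)
  best <- sum(apply(x$score, 1L, max))
  expect_equal(as.numeric(thr), round(best / 1e-3) * 1e-3, tolerance = 1e-9)
})

test_that("scanning finds a planted consensus on both strands", {
  m <- default_motifs()
  cons <- consensus_of(m$AP1)
  thr <- score_threshold_from_pvalue(m$AP1, 1e-4)
  sq <- paste0(strrep("A", 30), cons, strrep("A", 30))
  h <- scan_sequence(m$AP1, sq, thr)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 30L)
  expect_equal(h$strand, "+")
  expect_equal(h$score, sum(apply(m$AP1$score, 1L, max)), tolerance = 1e-9)

  sq_rc <- paste0(strrep("A", 30), reverse_complement(cons), strrep("A", 30))
  h2 <- scan_sequence(m$AP1, sq_rc, thr)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$position, 30L)
  expect_equal(h2$score, h$score, tolerance = 1e-9)
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(41)
  x <- random_pwm(6)
  sq <- random_dna(400)
  thr <- score_threshold_from_pvalue(x, 0.02)
  fwd <- scan_sequence(x, sq, thr)
  rev_ <- scan_sequence(x, reverse_complement(sq), thr)
  expect_equal(nrow(fwd), nrow(rev_))
  # positions mirror: start' = L - W - start, strands swap, scores equal
  mirrored <- data.frame(position = 400 - 6 - rev_$position,
                         strand = ifelse(rev_$strand == "+", "-", "+"),
                         score = rev_$score)
  mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
  expect_equal(fwd$position, mirrored$position)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
})

test_that("windows containing N are skipped and short sequences yield no hits", {
  m <- default_motifs()
  thr <- score_threshold_from_pvalue(m$AP1, 1e-4)
  cons <- consensus_of(m$AP1)
  broken <- sub("C", "N", cons) # N inside the instance window
  expect_equal(nrow(scan_sequence(m$AP1, paste0("AAAA", broken, "AAAA"), thr)), 0L)
  expect_equal(nrow(scan_sequence(m$AP1, "ACGT", thr)), 0L)
})

test_that("peak profiles record thresholded hits, counts and best raw scores", {
  m <- default_motifs()
  set.seed(55)
  plant <- list(
    data.frame(instance = consensus_of(m$AP1), offset = -20),
    data.frame(instance = c(consensus_of(m$AP1), consensus_of(m$TEAD)),
               offset = c(-40, 15)),
    NULL)
  seqs <- windows_with_plants(3, 150, plant)
  prof <- scan_peaks(seqs, m, pvalue = 1e-4)
  expect_equal(unname(prof$n_hits[1, "AP1"]), 1L)
  expect_equal(unname(prof$n_hits[2, c("AP1", "TEAD")]), c(1L, 1L))
  # best raw equals the max hit score where hits exist
  h <- prof$hits$AP1
  expect_equal(unname(prof$best_raw[1, "AP1"]),
               max(h$score[h$peak == 1]), tolerance = 1e-9)
  # center offsets recover the planted positions
  expect_equal(h$center_offset[h$peak == 1], -20)
  expect_equal(prof$hits$TEAD$center_offset[prof$hits$TEAD$peak == 2], 15)
})

test_that("TEAD monomer-or-dimer rule and class labels follow the definitions", {
  m <- default_motifs()
  plant <- list(
    data.frame(instance = consensus_of(m$TEAD_DIMER), offset = 0),  # dimer only
    data.frame(instance = consensus_of(m$TEAD), offset = 0),        # monomer only
    NULL,                                                           # neither
    data.frame(instance = consensus_of(m$AP1), offset = -30),       # AP1 only
    data.frame(instance = c(consensus_of(m$AP1), consensus_of(m$TEAD)),
               offset = c(-40, 20)),                                # composite
    data.frame(instance = c(consensus_of(m$AP1), consensus_of(m$TEAD),
                            consensus_of(m$STAT3)),
               offset = c(-60, 0, 60)))                             # triple
  set.seed(60)
  seqs <- windows_with_plants(6, 150, plant)
  prof <- scan_peaks(seqs, m, pvalue = 1e-4)
  expect_equal(has_tead_motif(prof), c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  cls <- classify_peaks(prof)
  expect_equal(as.character(cls[3:6]),
               c("none", "AP1_only", "AP1_TEAD", "AP1_TEAD_STAT3"))
})

test_that("classification is monotone: adding a hit never removes a motif", {
  m <- default_motifs()
  set.seed(61)
  for (i in 1:20) {
    base_plant <- if (runif(1) < 0.5) {
      list(data.frame(instance = consensus_of(m$AP1), offset = -50))
    } else list(NULL)
    seq1 <- windows_with_plants(1, 150, base_plant)
    # add a STAT3 instance far from the AP-1 one
    with_extra <- base_plant
    extra <- data.frame(instance = consensus_of(m$STAT3), offset = 70)
    with_extra[[1]] <- rbind(with_extra[[1]], extra)
    seq2 <- seq1
    inst <- strsplit(extra$instance, "")[[1]]
    s <- strsplit(seq2, "")[[1]]
    st <- 151 + extra$offset - 6
    s[st:(st + 12)] <- inst
    seq2 <- paste(s, collapse = "")
    names(seq2) <- names(seq1)
    l1 <- as.character(classify_peaks(scan_peaks(seq1, m)))
    l2 <- as.character(classify_peaks(scan_peaks(seq2, m)))
    motifs_of <- function(l) setdiff(strsplit(l, "_")[[1]], c("only", "none"))
    expect_true(all(motifs_of(l1) %in% motifs_of(l2)))
  }
})

test_that("positional histograms bin motif centers around the summit", {
  m <- default_motifs()[c("AP1")]
  set.seed(70)
  plant <- replicate(40, data.frame(instance = consensus_of(default_motifs()$AP1),
                                    offset = 0), simplify = FALSE)
  seqs <- windows_with_plants(40, 500, plant)
  prof <- scan_peaks(seqs, m, pvalue = 1e-4)
  h <- positional_histogram(prof, "AP1", window_bp = 500, bin_bp = 10)
  central <- h$bin_start <= 0 & h$bin_end > 0
  # all 40 planted instances land in the central bin; rare background hits
  # elsewhere in the +/-500 windows are tolerated
  expect_gte(h$count[central], 40)
  expect_equal(max(h$count), h$count[central])
  # no hits -> all-zero histogram
  set.seed(71)
  empty <- scan_peaks(windows_with_plants(5, 500), m, pvalue = 1e-6)
  h0 <- positional_histogram(empty, "AP1")
  expect_true(all(h0$count == 0))
  # non-dividing bin width warns
  expect_warning(positional_histogram(prof, "AP1", 500, 7), "truncated")
})

test_that("composite spacing is the minimum-magnitude signed center distance", {
  m <- default_motifs()
  cons_a <- consensus_of(m$AP1)
  cons_t <- consensus_of(m$TEAD)
  set.seed(80)
  plant <- list(
    data.frame(instance = c(cons_a, cons_t), offset = c(-20, 15)),
    data.frame(instance = c(cons_a, cons_t, cons_t), offset = c(0, 15, 90)),
    data.frame(instance = cons_a, offset = 0)) # no TEAD: skipped
  seqs <- windows_with_plants(3, 150, plant)
  prof <- scan_peaks(seqs, m, pvalue = 1e-4)
  sp <- composite_spacing(prof)
  expect_equal(length(sp), 2L)
  expect_equal(unname(sp[1]), 35)  # +15 - (-20)
  expect_equal(unname(sp[2]), 15)  # min magnitude among +15, +90
})

test_that("JASPAR parsing and the bundled motif set agree on shape", {
  m <- default_motifs()
  expect_named(m, c("AP1", "TEAD", "TEAD_DIMER", "STAT3", "CEBP", "NFKB"))
  for (x in m) {
    expect_s3_class(x, "pwm")
    expect_equal(x$width, 13L)
    expect_equal(rowSums(x$probs_reg), rep(1, 13), tolerance = 1e-6)
  }
})
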