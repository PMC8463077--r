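# Motif-class signatures, GSS, Kaplan-Meier and log-rank.

test_that("motif signatures follow the has-A-but-not-B rule", {
  classes <- c("AP1_only", "AP1_TEAD", "TEAD_only", "AP1_STAT3", "none")
  links <- data.frame(peak = c(1L, 2L, 3L, 4L, 5L, 1L, 3L),
                      gene_id = c("gA", "gB", "gC", "gD", "gE", "gAB", "gAB"))
  sig_a <- define_motif_signature(classes, links, "AP1_only")
  expect_setequal(sig_a$genes, c("gA", "gD", "gAB")) # AP1_STAT3 qualifies too
  sig_t <- define_motif_signature(classes, links, "TEAD_only")
  expect_setequal(sig_t$genes, c("gC", "gAB"))
  # gAB has one AP-1 peak and one TEAD peak: member of both signatures
  expect_true("gAB" %in% intersect(sig_a$genes, sig_t$genes))
  sig_b <- define_motif_signature(classes, links, "AP1_and_TEAD")
  expect_setequal(sig_b$genes, "gB") # composite peaks only
  expect_error(define_motif_signature(rep("none", 5), links, "AP1_only"),
               "larger")
})

test_that("signatures split by motif-site count allow dual membership", {
  m <- default_motifs()
  cons <- consensus_of(m$AP1)
  set.seed(151)
  plant <- list(
    data.frame(instance = cons, offset = 0),                    # 1 hit
    data.frame(instance = cons, offset = c(-80, 0, 80)),        # 3 hits
    data.frame(instance = cons, offset = -40),                  # 1 hit
    data.frame(instance = cons, offset = c(-60, 60)))           # 2 hits
  prof <- scan_peaks(windows_with_plants(4, 150, plant), m)
  classes <- as.character(classify_peaks(prof))
  links <- data.frame(peak = c(1L, 2L, 3L, 4L),
                      gene_id = c("g1", "g2", "gBoth", "gBoth"))
  sig <- define_motif_signature(classes, links, "AP1_only")
  sp <- split_by_motif_count(sig, prof, classes, links, "AP1")
  expect_true("g1" %in% sp$one_motif)
  expect_true("g2" %in% sp$multi_motif)
  expect_true("gBoth" %in% sp$one_motif && "gBoth" %in% sp$multi_motif)
})

test_that("CV filter removes flat and hyper-variable genes", {
  expr <- rbind(flat = rep(7, 4),
                low = c(10, 10.1, 9.9, 10),       # CV ~ 0.008
                keep = c(10, 20, 10, 20),          # CV ~ 0.385
                wild = c(1, 100, 1, 100),          # CV ~ 1.13
                zero = rep(0, 4))
  kept <- cv_filter(expr)
  expect_equal(kept, "keep")
  # hand-computed boundary: values (10, 20) give CV = 7.071/15 = 0.471
  expect_equal(sd(c(10, 20)) / mean(c(10, 20)), 0.4714, tolerance = 1e-4)
  expect_true("g" %in% cv_filter(rbind(g = c(10, 20))))
  expect_error(cv_filter(rbind(g = 1)), "patients")
})

test_that("GSS matches the hand-computed example and its identities", {
  expr <- rbind(g1 = c(1, 3), g2 = c(2, 6))
  colnames(expr) <- c("p1", "p2")
  out <- gss(expr, c("g1", "g2"))
  expect_equal(out$gss[1], -(1 / sqrt(2)) * 2, tolerance = 1e-9) # -1.414
  expect_equal(as.character(out$group), c("low", "high"))
  expect_equal(sum(out$gss), 0, tolerance = 1e-9)

  # cohort z-score identity on random matrices; boundary 0 goes high
  set.seed(161)
  m <- matrix(rlnorm(50 * 30), 50, dimnames = list(sprintf("g%d", 1:50),
                                                   sprintf("p%d", 1:30)))
  res <- gss(m, sprintf("g%d", 1:20))
  expect_equal(sum(res$gss), 0, tolerance = 1e-9)
  expect_true(all((res$gss >= 0) == (res$group == "high")))
  # constant signature gene points at the CV filter
  m2 <- rbind(m, gconst = rep(1, 30))
  expect_error(gss(m2, c("g1", "gconst")), "cv_filter")
})

test_that("product-limit estimates match closed forms", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(km$survival) <= 0))

  all_cens <- km_estimate(c(5, 8, 2), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0L) # no event times: S stays 1
  expect_equal(km_survival_at(all_cens, c(1, 10)), c(1, 1))

  mixed <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(mixed$survival, c(2 / 3, 0))
  expect_error(km_estimate(-1, 1), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(171)
  t <- rexp(60, 0.1)
  km <- km_estimate(t, rep(1, 60))
  grid <- quantile(t, c(0.1, 0.35, 0.6, 0.9))
  expect_equal(km_survival_at(km, grid),
               vapply(grid, function(g) mean(t > g), numeric(1)))
})

test_that("KM agrees with survival::survfit on censored data", {
  set.seed(172)
  t <- round(rexp(80, 0.05), 1)
  e <- rbinom(80, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  idx <- match(km$time, sf$time)
  expect_equal(km$survival, sf$surv[idx], tolerance = 1e-10)
})

test_that("log-rank: symmetry, relabeling invariance, survdiff agreement", {
  t <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e <- rep(1, 8)
  g <- rep(c("a", "b"), 4)
  same <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)

  set.seed(181)
  t2 <- rexp(100, rep(c(0.05, 0.1), each = 50))
  e2 <- rbinom(100, 1, 0.8)
  g2 <- rep(c("a", "b"), each = 50)
  lr <- logrank_test(t2, e2, g2)
  lr_swap <- logrank_test(t2, e2, ifelse(g2 == "a", "b", "a"))
  expect_equal(lr$statistic, lr_swap$statistic, tolerance = 1e-12)
  sd_ <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  expect_error(logrank_test(t2, rep(0, 100), g2), "events")
})

test_that("planted hazard on high-GSS patients separates the curves correctly", {
  set.seed(191)
  hits <- 0
  direction <- 0
  for (i in 1:20) {
    n_p <- 150
    genes <- sprintf("g%d", 1:40)
    u <- rnorm(n_p)
    expr <- matrix(rlnorm(40 * n_p, log(50), 0.3), 40,
                   dimnames = list(genes, sprintf("p%d", 1:n_p)))
    sig <- genes[1:15]
    expr[sig, ] <- expr[sig, ] * matrix(exp(0.5 * u), 15, n_p, byrow = TRUE)
    g_tab <- gss(expr, sig)
    haz <- 0.02 * ifelse(g_tab$gss >= 0, 3, 1)
    t <- rexp(n_p, haz)
    c_ <- rexp(n_p, 0.005)
    time <- pmin(t, c_); ev <- as.integer(t <= c_)
    lr <- logrank_test(time, ev, g_tab$group)
    hits <- hits + (lr$pvalue < 0.05)
    km_hi <- km_estimate(time[g_tab$group == "high"], ev[g_tab$group == "high"])
    km_lo <- km_estimate(time[g_tab$group == "low"], ev[g_tab$group == "low"])
    tm <- median(time)
    direction <- direction + (km_survival_at(km_hi, tm) < km_survival_at(km_lo, tm))
  }
  expect_gte(hits, 19)       # HR = 3 is detected essentially always
  expect_gte(direction, 19)  # and the high-GSS group fares worse
})
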