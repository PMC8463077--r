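# Independent oracles and small constructors shared across tests.

# Exhaustive enumeration of the null score distribution of a PWM over all
# 4^W windows, on the same discretization as the package's DP. Returns the
# smallest achievable integer score (units of step_bits) whose tail
# probability is <= p, and that tail. Independent of the DP implementation.
enum_threshold_units <- function(x, p, step_bits = 1e-3) {
  S <- round(x$score / step_bits)
  W <- x$width
  idx <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- numeric(nrow(idx))
  pr <- rep(1, nrow(idx))
  for (j in seq_len(W)) {
    sc <- sc + S[j, idx[, j]]
    pr <- pr * x$background[idx[, j]]
  }
  agg <- rowsum(pr, sc)
  scores <- as.numeric(rownames(agg))
  ord <- order(scores)
  scores <- scores[ord]
  mass <- as.numeric(agg[ord, 1L])
  tails <- rev(cumsum(rev(mass)))
  ok <- which(tails <= p)
  if (length(ok) == 0L) {
    list(units = max(scores) + 1L, tail = 0)
  } else {
    list(units = unname(scores[ok[1L]]), tail = unname(tails[ok[1L]]))
  }
}

# Random PWM with Dirichlet-ish rows (gamma normalization).
random_pwm <- function(width, name = "rand", conc = 0.5, pseudocount = 0.01) {
  m <- matrix(rgamma(width * 4, conc), width, 4)
  pwm(name, m / rowSums(m), pseudocount = pseudocount)
}

# Consensus string of a PWM.
consensus_of <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$probs, 1L, which.max)], collapse = "")
}

reverse_complement <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# Random DNA of length n (uses the current RNG state).
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Build summit-window sequences (length 2*hw+1) with the given motif
# instances planted at center offsets; `plant` is a list (one element per
# peak) of data.frames with columns instance, offset.
windows_with_plants <- function(n, hw, plant = vector("list", n)) {
  out <- character(n)
  for (i in seq_len(n)) {
    s <- strsplit(random_dna(2 * hw + 1), "")[[1L]]
    pl <- plant[[i]]
    if (!is.null(pl)) {
      for (k in seq_len(nrow(pl))) {
        inst <- strsplit(pl$instance[k], "")[[1L]]
        start <- hw + 1 + pl$offset[k] - (length(inst) - 1L) %/% 2L
        s[start:(start + length(inst) - 1L)] <- inst
      }
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- sprintf("pk%04d", seq_len(n))
  out
}

# Exact permutation-style Monte-Carlo p-value for the two-group log-rank
# statistic (relabeling oracle).
permutation_logrank_p <- function(time, event, group, n_perm = 10000) {
  obs <- logrank_test(time, event, group)$statistic
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(group)
    if (logrank_test(time, event, g)$statistic >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / n_perm
}

# Shared default-size synthetic dataset for expensive acceptance checks
# (generated once per test run).
.acc_env <- new.env(parent = emptyenv())
acceptance_dataset <- function() {
  if (is.null(.acc_env$ds)) {
    .acc_env$ds <- generate_dataset(synth_config(seed = 1))
  }
  .acc_env$ds
}
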