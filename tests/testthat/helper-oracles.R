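# Independent oracles used across the suite. These are deliberately written
# from first principles and never call the code paths they check.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins.
fisher_oracle <- function(x1, r1, x2, r2) {
  c1 <- x1 + x2
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(k, r1, r2, c1)
  obs <- pr[k == x1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Hand-coded two-group log-rank chi-square (hypergeometric moments).
logrank_stat_oracle <- function(time, event, g1) {
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Exhaustive permutation p-value for the log-rank test on tiny cohorts.
logrank_perm_oracle <- function(time, event, group) {
  g1_idx <- which(group == levels(factor(group))[1])
  n <- length(time); k <- length(g1_idx)
  obs <- logrank_stat_oracle(time, event, seq_len(n) %in% g1_idx)
  combs <- utils::combn(n, k)
  stats_all <- apply(combs, 2, function(idx)
    logrank_stat_oracle(time, event, seq_len(n) %in% idx))
  mean(stats_all >= obs - 1e-12)
}

# Kaplan-Meier by the product-limit definition, events only.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  vapply(ts, function(t) {
    n <- sum(time >= t); d <- sum(time == t & event == 1)
    s <<- s * (1 - d / n)
    s
  }, numeric(1))
}

# Overlapping occurrence count via an explicit position scan.
scan_count_oracle <- function(kmer, s) {
  w <- nchar(kmer); L <- nchar(s)
  if (L < w) return(0L)
  hits <- 0L
  for (i in 1:(L - w + 1)) if (substr(s, i, i + w - 1) == kmer) hits <- hits + 1L
  hits
}

tiny_config <- function(n = 40, seed = 11, ...) {
  sim_config(n_events = n, seed = seed, exon_len = 60, flank_len = 60, ...)
}
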