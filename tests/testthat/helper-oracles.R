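# Independent transcriptions of published estimators, used as oracles.
# These deliberately mirror the printed equations step by step (scalar code,
# no shared helpers with the package implementation).

# Weir & Cockerham (1984) two-allele variance components for r populations,
# from per-population dosage vectors.
wc_oracle <- function(genos) {
  r <- length(genos)
  n <- sapply(genos, length)
  p <- sapply(genos, function(g) sum(g) / (2 * length(g)))
  h <- sapply(genos, function(g) mean(g == 1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force greedy LD pruner: checks the window - 1 most recently retained
# sites directly with stats::cor
ld_prune_oracle <- function(gm, r2_max = 0.2, window = 1000) {
  d <- gm$dosages
  kept <- integer(0)
  for (j in seq_len(ncol(d))) {
    cand <- utils::tail(kept, window - 1)
    ok <- TRUE
    for (k in cand) {
      x <- d[, k]; y <- d[, j]
      cc <- stats::complete.cases(x, y)
      r2 <- if (sum(cc) < 3 || stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) {
        0
      } else {
        stats::cor(x[cc], y[cc])^2
      }
      if (r2 >= r2_max - 1e-9) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

# bias-corrected f2 from explicit dosage sets (scalar, per the standard
# sample-frequency correction)
f2_oracle <- function(dA, dB) {
  nA <- 2 * length(dA); nB <- 2 * length(dB)
  pA <- sum(dA) / nA; pB <- sum(dB) / nB
  (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
}

# dosage vector realizing an exact allele frequency p over n diploids
# (p * 2n must be an integer)
exact_freq_dosages <- function(p, n) {
  alt <- round(p * 2 * n)
  d <- integer(n)
  d[seq_len(alt %/% 2)] <- 2L
  if (alt %% 2 == 1) d[alt %/% 2 + 1] <- 1L
  d
}
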