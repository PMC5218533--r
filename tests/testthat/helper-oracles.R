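# Independent brute-force oracles used to cross-check the implementation.

# circular mean/concentration by explicit elementwise summation
circ_oracle <- function(phases) {
  sc <- 0
  ss <- 0
  for (p in phases) {
    sc <- sc + cos(2 * pi * p)
    ss <- ss + sin(2 * pi * p)
  }
  mc <- sc / length(phases)
  ms <- ss / length(phases)
  list(r = sqrt(mc^2 + ms^2), phi = (atan2(ms, mc) / (2 * pi)) %% 1)
}

# two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins (probability-mass rule)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# permutation test for equality of two regression slopes
slope_perm_oracle <- function(x1, y1, x2, y2, n_perm = 1000, seed = 1) {
  slope <- function(x, y) stats::cov(x, y) / stats::var(x)
  obs <- abs(slope(x1, y1) - slope(x2, y2))
  x <- c(x1, x2); y <- c(y1, y2)
  n1 <- length(x1)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(x), n1)
    d <- abs(slope(x[idx], y[idx]) - slope(x[-idx], y[-idx]))
    if (d >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
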