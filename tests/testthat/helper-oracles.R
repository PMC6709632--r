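# Independent brute-force oracles, deliberately written on different code
# paths than the implementations they check.

# Direct normalized autocorrelation at integer lag k via explicit loops
# (symmetric normalization, as defined on the correlation-curve type).
oracle_corr_at <- function(x, k) {
  n <- length(x)
  s_ab <- s_a <- s_b <- 0
  for (i in 1:(n - k)) {
    s_ab <- s_ab + x[i] * x[i + k]
    s_a <- s_a + x[i]
    s_b <- s_b + x[i + k]
  }
  m <- n - k
  (s_ab / m) / ((s_a / m) * (s_b / m)) - 1
}

# Brute-force recomputation of the multi-tau estimator: same lag schedule
# (lags 1..2m raw, then (m+1)..2m per halving), with the binning done via
# matrix folding rather than the package's stride indexing.
oracle_multitau <- function(x, dt, m) {
  lag <- G <- numeric(0)
  cur <- x
  curdt <- dt
  ks <- 1:(2 * m)
  repeat {
    ks <- ks[ks < length(cur)]
    if (!length(ks)) break
    for (k in ks) {
      G <- c(G, oracle_corr_at(cur, k))
      lag <- c(lag, k * curdt)
    }
    nn <- 2 * (length(cur) %/% 2)
    if (nn < 2 * (m + 1)) break
    cur <- colMeans(matrix(cur[1:nn], nrow = 2))
    curdt <- 2 * curdt
    ks <- (m + 1):(2 * m)
  }
  list(lag = lag, G = G)
}

# symmetric two-state telegraph signal: states 0/1, switch rate k_sw per s
make_telegraph <- function(n, dt, k_sw, levels = c(0, 10)) {
  p <- k_sw * dt
  flips <- runif(n) < p
  state <- cumsum(c(sample(0:1, 1), flips[-1])) %% 2
  levels[state + 1]
}

# least-squares slope of MSD(t); D = slope / 4 in 2D
msd_D <- function(msd_df) unname(coef(lm(msd ~ time, msd_df))[2] / 4)
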