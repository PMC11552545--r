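# shared fixture builders (all programmatic; no stored data)

# random point on the n-simplex
r_simplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# ensemble of k random (p0, p1) simplex pairs, as used by the estimator
r_ensemble <- function(n, k) {
  P0 <- replicate(k, r_simplex(n))
  P1 <- replicate(k, r_simplex(n))
  list(P0 = P0, P1 = P1, dP = P1 - P0, n_states = n, k = k)
}

# brute-force per-spike construction: L_s = sum_j (p1 - e_j) p0[j] e_j^T,
# averaged over spikes -- the term-by-term state summation the direct
# linear estimator must reproduce
brute_force_sdo <- function(P0, P1) {
  n <- nrow(P0)
  k <- ncol(P0)
  acc <- matrix(0, n, n)
  for (s in seq_len(k)) {
    for (j in seq_len(n)) {
      ej <- numeric(n); ej[j] <- 1
      acc <- acc + P0[j, s] * (P1[, s] - ej) %*% t(ej)
    }
  }
  acc / k
}

# a smooth state series with a known operator-friendly structure
sine_state_series <- function(n_states = 12, len = 6000, fs = 1000) {
  x <- sin(seq(0, 40 * pi, length.out = len)) + rnorm(len, sd = 0.3)
  q <- build_quantizer(x, n_states)
  quantize(x, q, fs = fs)
}

# valid random SDO in conditional form: random nonnegative off-diagonal
# columns with mass <= 1, diagonal balancing to zero column sums
r_valid_sdo <- function(n, mass = 0.5) {
  W <- matrix(rexp(n * n), n, n)
  diag(W) <- 0
  W <- sweep(W, 2, colSums(W), `/`) * mass
  diag(W) <- -colSums(W)
  W
}
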