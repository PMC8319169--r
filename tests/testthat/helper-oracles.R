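# Brute-force oracles used to cross-check the vectorized statistic paths.

# weighted covariance of a map with its shifted copy, by explicit loops
# over pixels (circular neighbors taken from the full map)
brute_weighted_cov <- function(q, w, dy, dx) {
  n <- nrow(q)
  tot <- 0; sw <- 0; s1 <- 0; s2 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (w[i, j] == 0) next
    i2 <- ((i - 1 + dy) %% n) + 1
    j2 <- ((j - 1 + dx) %% n) + 1
    tot <- tot + w[i, j] * q[i, j] * q[i2, j2]
    s1 <- s1 + w[i, j] * q[i, j]
    s2 <- s2 + w[i, j] * q[i2, j2]
    sw <- sw + w[i, j]
  }
  tot / sw - (s1 / sw) * (s2 / sw)
}

# seeded test image in the package gray convention
gray_noise <- function(n, seed = 1, mean = 0.5, sd = 0.15) {
  set.seed(seed)
  matrix(stats::rnorm(n * n, mean, sd), n)
}
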