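# Shared fixtures and independent oracles used across the test files.

# Random symmetric positive definite matrix with eigenvalues bounded away
# from zero.
rand_spd <- function(d, jitter = 0.5) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + jitter * diag(d)
}

# Brute-force matrix normal log-density through the vectorized
# pq-variate normal with covariance V (x) U, assembled explicitly.
vec_normal_logpdf <- function(X, M, U, V) {
  S <- kronecker(V, U)
  d <- length(X)
  r <- as.numeric(X - M)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (d * log(2 * pi) + ld + sum(r * solve(S, r)))
}

# A small random mixture model built directly from matnorm parameter sets.
rand_mixture <- function(G, p, q, penalties = penalty_config()) {
  components <- lapply(seq_len(G), function(j)
    pmnmm:::new_component(matrix(rnorm(p * q), p, q), rand_spd(p), rand_spd(q)))
  w <- rexp(G) + 0.2
  pmnmm:::new_mixture_model(w / sum(w), components, penalties)
}

# Random small sample stack.
rand_samples <- function(n, p, q) {
  as_matrix_samples(array(rnorm(p * q * n), dim = c(p, q, n)))
}

# Independent (per-slice) vectorization, n x pq.
vectorize_samples_oracle <- function(samples) {
  d <- dim(samples)
  t(sapply(seq_len(d[3]), function(i) as.numeric(samples[, , i])))
}

# Well-separated two-cluster stack for initialization/matching tests.
separated_samples <- function(n_per = 15, p = 4, q = 4, gap = 50) {
  a <- array(rnorm(p * q * n_per), dim = c(p, q, n_per))
  b <- array(rnorm(p * q * n_per) + gap, dim = c(p, q, n_per))
  list(samples = as_matrix_samples(array(c(a, b), dim = c(p, q, 2 * n_per))),
       labels = rep(1:2, each = n_per))
}
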