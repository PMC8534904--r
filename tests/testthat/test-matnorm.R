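test_that("log-density matches closed-form values at the mean and identity case", {
  p <- 3; q <- 4
  set.seed(1)
  U <- rand_spd(p); V <- rand_spd(q)
  M <- matrix(rnorm(p * q), p, q)
  pr <- matnorm_params(M, U, V)
  expected <- -(p * q / 2) * log(2 * pi) -
    (p / 2) * as.numeric(determinant(V)$modulus) -
    (q / 2) * as.numeric(determinant(U)$modulus)
  expect_equal(matnorm_logpdf(M, pr), expected, tolerance = 1e-12)

  pr2 <- matnorm_params(matrix(0, 2, 2), diag(2), diag(2))
  expect_equal(matnorm_logpdf(diag(2), pr2), -2 * log(2 * pi) - 1,
               tolerance = 1e-12)
})

test_that("log-density agrees with the vectorized pq-variate normal oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- sample(2:5, 1); q <- sample(2:5, 1)
    U <- rand_spd(p); V <- rand_spd(q)
    M <- matrix(rnorm(p * q), p, q)
    X <- matrix(rnorm(p * q, sd = 2), p, q)
    expect_equal(matnorm_logpdf(X, matnorm_params(M, U, V)),
                 vec_normal_logpdf(X, M, U, V), tolerance = 1e-8)
  }
})

test_that("density integrates to one (importance-sampling check, 2x2)", {
  set.seed(7)
  U <- rand_spd(2); V <- rand_spd(2)
  M <- matrix(c(0.3, -0.1, 0.2, 0), 2, 2)
  target <- matnorm_params(M, U, V)
  proposal <- matnorm_params(M, 3 * U, 3 * V)
  draws <- sample_matnorm(proposal, 40000, seed = 11)
  lw <- matnorm_logpdf(draws, target) - matnorm_logpdf(draws, proposal)
  expect_equal(mean(exp(lw)), 1, tolerance = 0.02)
})

test_that("log-density rejects malformed inputs by name", {
  pr <- matnorm_params(matrix(0, 2, 2), diag(2), diag(2))
  expect_error(matnorm_logpdf(matrix(0, 3, 2), pr), "2x2")
  bad_U <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(matnorm_params(matrix(0, 2, 2), bad_U, diag(2)),
               "U is not positive definite")
  expect_error(matnorm_params(matrix(0, 2, 2), diag(2), -diag(2)),
               "V is not positive definite")
})

test_that("sampling is reproducible and has the advertised moments", {
  pr <- matnorm_params(matrix(0, 3, 3), diag(3), diag(3))
  a <- sample_matnorm(pr, 50, seed = 3)
  b <- sample_matnorm(pr, 50, seed = 3)
  expect_identical(unclass(a), unclass(b))

  big <- sample_matnorm(pr, 10000, seed = 4)
  v <- apply(unclass(big), c(1, 2), var)
  expect_true(all(v > 0.94 & v < 1.06))
})

test_that("empirical covariance of vec samples approaches the Kronecker product", {
  set.seed(9)
  U <- rand_spd(3); V <- rand_spd(3)
  pr <- matnorm_params(matrix(0, 3, 3), U, V)
  draws <- sample_matnorm(pr, 5000, seed = 10)
  emp <- cov(t(matrix(unclass(draws), 9, 5000)))
  K <- kronecker(V, U)
  expect_lt(norm(emp - K, "F") / norm(K, "F"), 0.1)
})

test_that("flip-flop MLE recovers the Kronecker covariance up to scale", {
  set.seed(12)
  p <- 4; q <- 4
  U <- rand_spd(p); V <- rand_spd(q)
  M <- matrix(rnorm(p * q), p, q)
  draws <- sample_matnorm(matnorm_params(M, U, V), 2000, seed = 13)
  fit <- fit_matnorm_mle(draws)
  K_true <- kronecker(V, U)
  K_hat <- kronecker(fit$V, fit$U)
  expect_lt(norm(K_hat - K_true, "F") / norm(K_true, "F"), 0.1)
  expect_equal(fit$M, M, tolerance = 0.2)
  expect_equal(sum(diag(fit$U)), p, tolerance = 1e-10)
})

test_that("degenerate inputs raise rank-deficiency errors", {
  X <- array(1, dim = c(3, 3, 5))  # identical samples, zero scatter
  expect_error(fit_matnorm_mle(X), "rank-deficient")
  expect_error(fit_matnorm_mle(rand_samples(1, 2, 2)), "rank-deficient")
})

test_that("flip-flop MLE is invariant to sample order", {
  set.seed(21)
  draws <- sample_matnorm(matnorm_params(matrix(0, 3, 3), rand_spd(3),
                                         rand_spd(3)), 200, seed = 22)
  f1 <- fit_matnorm_mle(draws)
  f2 <- fit_matnorm_mle(unclass(draws)[, , sample(200)])
  expect_equal(f1$U, f2$U, tolerance = 1e-10)
  expect_equal(f1$V, f2$V, tolerance = 1e-10)
})

test_that("scale normalization fixes trace(U) = p without moving the Kronecker product", {
  out <- normalize_scale(2 * diag(3), diag(2))
  expect_equal(out$U, diag(3))
  expect_equal(out$V, 2 * diag(2))

  set.seed(31)
  U <- rand_spd(4); V <- rand_spd(3)
  out <- normalize_scale(U, V)
  expect_equal(sum(diag(out$U)), 4, tolerance = 1e-12)
  expect_equal(kronecker(out$V, out$U), kronecker(V, U), tolerance = 1e-12)
  # idempotent
  out2 <- normalize_scale(out$U, out$V)
  expect_equal(out2$U, out$U, tolerance = 1e-14)
  expect_equal(out2$V, out$V, tolerance = 1e-14)
})
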