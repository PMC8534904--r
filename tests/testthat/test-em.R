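test_that("responsibilities reduce to trivial cases and match the density-ratio oracle", {
  set.seed(1)
  xs <- rand_samples(6, 3, 3)
  m1 <- rand_mixture(1, 3, 3)
  expect_equal(unname(e_step(xs, m1)), matrix(1, 6, 1))

  cmp <- pmnmm:::new_component(matrix(0, 3, 3), rand_spd(3), rand_spd(3))
  m2 <- pmnmm:::new_mixture_model(c(0.5, 0.5), list(cmp, cmp), penalty_config())
  expect_equal(unname(e_step(xs, m2)), matrix(0.5, 6, 2), tolerance = 1e-12)

  m3 <- rand_mixture(2, 3, 3)
  xs5 <- rand_samples(5, 3, 3)
  tau <- e_step(xs5, m3)
  for (i in 1:5) {
    ld <- sapply(1:2, function(j) {
      c3 <- m3$components[[j]]
      log(m3$weights[j]) + vec_normal_logpdf(xs5[, , i], c3$M, c3$U, c3$V)
    })
    expect_equal(tau[i, ], exp(ld) / sum(exp(ld)), tolerance = 1e-10)
  }
  expect_equal(rowSums(tau), rep(1, 5), tolerance = 1e-12)
})

test_that("weight update is the column mean of the responsibilities", {
  expect_equal(update_weights(matrix(0.5, 10, 2)), c(0.5, 0.5))
  tau <- matrix(0, 100, 2); tau[1:30, 1] <- 1; tau[31:100, 2] <- 1
  expect_equal(update_weights(tau), c(0.3, 0.7))
  set.seed(2)
  r <- matrix(runif(40), 10, 4); r <- r / rowSums(r)
  expect_equal(sum(update_weights(r)), 1, tolerance = 1e-12)
})

test_that("penalized mean update soft-thresholds the weighted mean", {
  set.seed(3)
  n <- 8; p <- 3; q <- 4
  xs <- rand_samples(n, p, q)
  model <- rand_mixture(2, p, q)
  tau <- e_step(xs, model)

  # lambda1 = 0: exact weighted means
  m0 <- update_means_penalized(xs, tau, model, 0)
  for (j in 1:2) {
    Mhat <- apply(sweep(unclass(xs), 3, tau[, j], "*"), c(1, 2), sum) / sum(tau[, j])
    expect_equal(m0[[j]], Mhat, tolerance = 1e-12)
  }

  # identity covariances collapse the threshold to a scalar lambda1 / sum(tau)
  id_model <- pmnmm:::new_mixture_model(
    c(0.5, 0.5),
    list(pmnmm:::new_component(matrix(0, p, q), diag(p), diag(q)),
         pmnmm:::new_component(matrix(1, p, q), diag(p), diag(q))),
    penalty_config())
  tau1 <- matrix(0.5, n, 2)
  lambda1 <- 1.3
  mm <- update_means_penalized(xs, tau1, id_model, lambda1)
  thr <- lambda1 / (n / 2)
  for (j in 1:2) {
    Mhat <- apply(unclass(xs), c(1, 2), mean)
    oracle <- sign(Mhat) * pmax(abs(Mhat) - thr, 0)  # scalar soft threshold
    expect_equal(mm[[j]], oracle, tolerance = 1e-12)
  }

  # enormous penalty: full shrinkage (identity factors keep the threshold
  # matrix strictly positive; negative threshold entries are clamped to
  # "no shrinkage" by design)
  minf <- update_means_penalized(xs, tau1, id_model, 1e12)
  for (j in 1:2) expect_true(all(minf[[j]] == 0))
})

test_that("zero-mean count is non-decreasing in lambda1 (sparsity monotonicity)", {
  set.seed(4)
  xs <- rand_samples(10, 4, 4)
  model <- rand_mixture(2, 4, 4)
  tau <- e_step(xs, model)
  lambdas <- c(0, 0.5, 1, 2, 5, 20, 100)
  zeros <- sapply(lambdas, function(l1) {
    sum(sapply(update_means_penalized(xs, tau, model, l1), function(m) sum(m == 0)))
  })
  expect_true(all(diff(zeros) >= 0))
})

test_that("weighted scatters match direct summation and their duality", {
  set.seed(5)
  n <- 6; p <- 3; q <- 4
  xs <- rand_samples(n, p, q)

  # one sample with M = X gives the zero matrix
  one <- xs[, , 1]
  z <- weighted_scatter_U(array(one, c(p, q, 1)), 1, one, rand_spd(q))
  expect_equal(unclass(z), matrix(0, p, p))

  # V = I, unit weights: plain averaged outer products over 1/(nq)
  M <- matrix(0.2, p, q)
  su <- weighted_scatter_U(xs, rep(1, n), M, diag(q))
  direct <- Reduce(`+`, lapply(1:n, function(i)
    tcrossprod(xs[, , i] - M))) / (n * q)
  expect_equal(unclass(su), direct, tolerance = 1e-12)
  expect_equal(unclass(su), t(unclass(su)))

  sv <- weighted_scatter_V(xs, rep(1, n), M, diag(p))
  directv <- Reduce(`+`, lapply(1:n, function(i)
    crossprod(xs[, , i] - M))) / (n * p)
  expect_equal(unclass(sv), directv, tolerance = 1e-12)

  # transpose duality: V-scatter equals U-scatter on transposed samples
  W <- rand_spd(p)
  xt <- array(0, c(q, p, n))
  for (i in 1:n) xt[, , i] <- t(xs[, , i])
  expect_equal(unclass(weighted_scatter_V(xs, rep(1, n), M, W)),
               unclass(weighted_scatter_U(xt, rep(1, n), t(M), W)),
               tolerance = 1e-12)
})

test_that("unpenalized precision update is one flip-flop round", {
  set.seed(6)
  n <- 30; p <- 3; q <- 3
  xs <- rand_samples(n, p, q)
  model <- rand_mixture(1, p, q)
  tau <- matrix(1, n, 1)
  M <- model$components[[1]]$M
  upd <- update_precisions(xs, tau, model, 0, 0, normalize = FALSE)[[1]]
  SU <- weighted_scatter_U(xs, rep(1, n), M, model$components[[1]]$Vinv)
  expect_equal(upd$U, unclass(SU), tolerance = 1e-8, ignore_attr = TRUE)
  SV <- weighted_scatter_V(xs, rep(1, n), M, solve(SU))
  expect_equal(upd$V, unclass(SV), tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("a large lambda2 gives a diagonal row precision", {
  set.seed(7)
  n <- 20
  xs <- rand_samples(n, 4, 4)
  model <- rand_mixture(1, 4, 4)
  tau <- matrix(1, n, 1)
  upd <- update_precisions(xs, tau, model, lambda2 = 1e5, lambda3 = 0)[[1]]
  off <- upd$Uinv - diag(diag(upd$Uinv))
  expect_true(all(off == 0))
  # and the invariant: normalized output, both factors PD
  expect_equal(sum(diag(upd$U)), 4, tolerance = 1e-10)
  expect_true(all(eigen(upd$V, TRUE, TRUE)$values > 0))
})

test_that("penalized log-likelihood decomposes into loglik minus penalties", {
  set.seed(8)
  xs <- rand_samples(5, 3, 3)
  model <- rand_mixture(2, 3, 3, penalty_config(0, 0, 0))
  base <- penalized_loglik(xs, model)
  oracle <- sum(sapply(1:5, function(i) {
    lv <- sapply(1:2, function(j) {
      cmp <- model$components[[j]]
      log(model$weights[j]) + vec_normal_logpdf(xs[, , i], cmp$M, cmp$U, cmp$V)
    })
    log(sum(exp(lv)))
  }))
  expect_equal(base, oracle, tolerance = 1e-8)

  model$penalties <- penalty_config(2, 3, 4)
  pen_terms <- 2 * sum(sapply(model$components, function(c) sum(abs(c$M)))) +
    3 * sum(sapply(model$components, function(c) sum(abs(c$Uinv)))) +
    4 * sum(sapply(model$components, function(c) sum(abs(c$Vinv))))
  expect_equal(penalized_loglik(xs, model), base - pen_terms, tolerance = 1e-8)
})

test_that("Aitken rule reproduces worked values and geometric limits", {
  expect_false(aitken_should_stop(c(1, 2), 0.001)$stop)

  st <- aitken_should_stop(c(1, 2, 2.5), 0.001)
  expect_equal(st$accelerated, 3)
  expect_false(st$stop)

  # geometric approach l(t) = L - c r^t: the accelerated value is exactly L
  L <- -100; cc <- 5; r <- 0.6
  hist <- L - cc * r^(1:10)
  st <- aitken_should_stop(hist, 1e-3)
  expect_equal(st$accelerated, L, tolerance = 1e-8)
  expect_true(st$stop)  # (L - l)/|l| = 5*0.6^10/100 << 1e-3
  st_early <- aitken_should_stop(hist[1:3], 1e-3)
  expect_equal(st_early$accelerated, L, tolerance = 1e-8)
  expect_false(st_early$stop)  # gap still 1.08% of |l|

  expect_true(aitken_should_stop(c(5, 5, 5), 1e-3)$stop)
})

test_that("K-means initialization is deterministic and splits separated clusters", {
  sep <- separated_samples()
  i1 <- init_kmeans(sep$samples, 2, seed = 11)
  i2 <- init_kmeans(sep$samples, 2, seed = 11)
  expect_equal(i1$components, i2$components)
  expect_equal(sort(i1$weights), c(0.5, 0.5))
  lab <- predict_labels(sep$samples, i1)
  expect_equal(clustering_accuracy(sep$labels, lab), 1)

  g1 <- init_kmeans(sep$samples, 1, seed = 12)
  mle <- fit_matnorm_mle(sep$samples)
  expect_equal(g1$components[[1]]$M, mle$M, tolerance = 1e-10)
})

test_that("an unpenalized single-component fit recovers the matrix normal MLE", {
  set.seed(13)
  draws <- sample_matnorm(matnorm_params(matrix(1, 3, 3), rand_spd(3),
                                         rand_spd(3)), 150, seed = 14)
  fit <- fit_pmnmm(draws, G = 1, penalty_config(0, 0, 0), n_restarts = 1,
                   seed = 15, epsilon = 1e-6)
  mle <- fit_matnorm_mle(draws, tol = 1e-6)
  expect_equal(fit$weights, 1)
  expect_equal(fit$components[[1]]$M, mle$M, tolerance = 1e-6)
  expect_equal(kronecker(fit$components[[1]]$V, fit$components[[1]]$U),
               kronecker(mle$V, mle$U), tolerance = 0.01)
  expect_equal(sum(diag(fit$components[[1]]$U)), 3, tolerance = 1e-10)
})

test_that("EM trace is monotone and the fit is equivariant to sample permutation", {
  sep <- separated_samples(n_per = 20, p = 4, q = 4, gap = 8)
  fit <- fit_pmnmm(sep$samples, 2, penalty_config(0.5, 0.05, 0.05),
                   n_restarts = 2, seed = 16)
  h <- fit$trace$loglik_history
  expect_true(all(diff(h) >= -1e-6 * abs(h[-1])))

  perm <- sample(dim(sep$samples)[3])
  fitp <- fit_pmnmm(unclass(sep$samples)[, , perm], 2,
                    penalty_config(0.5, 0.05, 0.05), n_restarts = 2, seed = 16)
  expect_equal(fit$trace$final_loglik, fitp$trace$final_loglik, tolerance = 1e-6)
  # components agree up to relabeling
  m_orig <- lapply(fit$components, `[[`, "M")
  m_perm <- lapply(fitp$components, `[[`, "M")
  mt <- match_components(predict_labels(sep$samples, fit),
                         predict_labels(sep$samples, fitp), 2)
  for (j in 1:2) expect_equal(m_perm[[mt[j]]], m_orig[[j]], tolerance = 1e-4)
})

test_that("MAP labels follow the posterior with ties toward the lower index", {
  tau <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  labels <- max.col(tau, ties.method = "first")
  expect_equal(labels, c(1L, 1L, 2L))
  sep <- separated_samples()
  fit <- init_kmeans(sep$samples, 2, seed = 17)
  lab <- predict_labels(sep$samples, fit)
  expect_equal(dim(attr(lab, "responsibilities")), c(30L, 2L))
  expect_true(all(lab %in% 1:2))
})
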