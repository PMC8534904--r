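#' Random k-fold partition
#'
#' Seeded uniform random split of `1..n` into `K` disjoint folds whose
#' sizes differ by at most one (unstratified; stratifying by cluster would
#' leak the labels the model is meant to discover).
#'
#' @param n number of samples.
#' @param K number of folds, `2 <= K <= n`.
#' @param seed integer seed.
#' @return A list of `K` integer index vectors.
#' @export
kfold_split <- function(n, K, seed = NULL) {
  if (K < 2 || K > n)
    stop(sprintf("K must be between 2 and n = %d, got %d", n, K))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  fold_of <- rep(seq_len(K), length.out = n)  # balanced sizes
  unname(lapply(split(idx, fold_of), unname))
}

#' Cross-validated model score
#'
#' The k-fold cross-validation score
#' \eqn{L_p^{(K)} = \frac1K \sum_k L_p(Y_k \mid Y_{-k})}: for each fold the
#' model is fitted on the remaining data (fresh seeded K-means
#' initializations) and the penalized log-likelihood of the held-out fold
#' is evaluated at the trained parameters (the penalty term entering once
#' per fold).  A fold whose fit fails contributes `-Inf` rather than
#' aborting the grid.
#'
#' @param samples a sample stack.
#' @param G number of components.
#' @param penalties a [penalty_config()].
#' @param K fold count (default 4).
#' @param seed integer seed controlling the partition and the fold fits.
#' @param ... passed to [fit_pmnmm()] (e.g. `n_restarts`, `max_iter`).
#' @return The mean held-out penalized log-likelihood (scalar).
#' @export
cv_score <- function(samples, G, penalties, K = 4, seed = 1, ...) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  folds <- kfold_split(d$n, K, seed)
  scores <- vapply(seq_len(K), function(k) {
    train <- subset_samples(samples, setdiff(seq_len(d$n), folds[[k]]))
    test <- subset_samples(samples, folds[[k]])
    fit <- tryCatch(
      fit_pmnmm(train, G, penalties, seed = seed + k, ...),
      error = function(e) NULL)
    if (is.null(fit)) return(-Inf)
    penalized_loglik(test, fit)
  }, 0)
  mean(scores)
}

#' Grid search over hyperparameters by cross-validation
#'
#' Exhaustive evaluation of [cv_score()] over the Cartesian product of the
#' component counts and the three penalty grids; the tuple with the
#' largest mean held-out penalized log-likelihood wins.  Score ties break
#' toward larger `(lambda1, lambda2, lambda3)` lexicographically (prefer
#' the sparser model).
#'
#' @param samples a sample stack.
#' @param G_values integer vector of component counts.
#' @param lambda1_grid,lambda2_grid,lambda3_grid penalty grids.
#' @param K fold count (default 4).
#' @param seed integer seed (same fold partition for every tuple).
#' @param verbose print progress per tuple.
#' @param ... passed to [fit_pmnmm()].
#' @return An object of class `pmnmm_cv`: a list with `grid` (a data frame
#'   of tuples and scores) and `best` (the selected row).
#' @export
grid_search <- function(samples, G_values, lambda1_grid, lambda2_grid,
                        lambda3_grid, K = 4, seed = 1, verbose = FALSE, ...) {
  if (!length(G_values) || !length(lambda1_grid) || !length(lambda2_grid) ||
      !length(lambda3_grid))
    stop("all grids must be non-empty")
  grid <- expand.grid(G = G_values, lambda1 = lambda1_grid,
                      lambda2 = lambda2_grid, lambda3 = lambda3_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$score[i] <- cv_score(samples, grid$G[i],
                              penalty_config(grid$lambda1[i], grid$lambda2[i],
                                             grid$lambda3[i]),
                              K = K, seed = seed, ...)
    if (verbose)
      message(sprintf("G=%d lambda=(%g, %g, %g): score %.4f", grid$G[i],
                      grid$lambda1[i], grid$lambda2[i], grid$lambda3[i],
                      grid$score[i]))
  }
  ord <- order(-grid$score, -grid$lambda1, -grid$lambda2, -grid$lambda3)
  structure(list(grid = grid, best = grid[ord[1], , drop = FALSE],
                 K = K, seed = seed),
            class = "pmnmm_cv")
}

#' @export
print.pmnmm_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d tuples; best:\n", x$K, nrow(x$grid)))
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Free-parameter counts of competing model families
#'
#' For clustering `n` matrices of size `p x q` into `G` groups:
#' \itemize{
#'   \item `"vectorized-GMM"`: a Gaussian mixture on `vec(X)`,
#'     \eqn{Gpq(pq+1)/2 + Gpq + G - 1} parameters;
#'   \item `"mean-penalized"`: Kronecker-separable covariance with `r`
#'     mean entries shrunk to zero,
#'     \eqn{Gp(p+1)/2 + Gq(q+1)/2 + Gpq + G - 1 - r};
#'   \item `"full-penalized"`: additionally shrinking precision entries,
#'     with `r_star` total zeroed parameters,
#'     \eqn{Gp(p+1)/2 + Gq(q+1)/2 + Gpq + G - 1 - r^*}.
#' }
#'
#' @param model_kind one of the three family names.
#' @param G,p,q model dimensions.
#' @param r number of zeroed mean parameters, `0 <= r <= Gpq`.
#' @param r_star number of zeroed mean and precision parameters,
#'   `r <= r_star <= Gp(p+1)/2 + Gq(q+1)/2 + Gpq`.
#' @return An integer count.
#' @examples
#' count_parameters("vectorized-GMM", G = 2, p = 20, q = 20)  # 161201
#' @export
count_parameters <- function(model_kind = c("vectorized-GMM", "mean-penalized",
                                            "full-penalized"),
                             G, p, q, r = 0, r_star = r) {
  model_kind <- match.arg(model_kind)
  if (r < 0 || r > G * p * q)
    stop(sprintf("r must lie in [0, %d]", G * p * q))
  sep <- G * p * (p + 1) / 2 + G * q * (q + 1) / 2 + G * p * q + G - 1
  switch(model_kind,
    "vectorized-GMM" = G * p * q * (p * q + 1) / 2 + G * p * q + G - 1,
    "mean-penalized" = sep - r,
    "full-penalized" = {
      rs_max <- G * p * (p + 1) / 2 + G * q * (q + 1) / 2 + G * p * q
      if (r_star < r || r_star > rs_max)
        stop(sprintf("r_star must lie in [%d, %d]", r, rs_max))
      sep - r_star
    })
}
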