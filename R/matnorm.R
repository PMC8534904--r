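#' Matrix normal parameters
#'
#' Bundles the parameters of a matrix normal distribution
#' \eqn{N_{p,q}(M, U, V)}: a `p x q` mean matrix `M`, a symmetric positive
#' definite `p x p` row covariance `U` and a `q x q` column covariance `V`.
#' The covariance of `vec(X)` is the Kronecker product \eqn{V \otimes U},
#' which is the only identified quantity: `(cU, V/c)` gives the same
#' distribution for any `c > 0` (see [normalize_scale()]).
#'
#' @param M numeric `p x q` mean matrix.
#' @param U symmetric positive definite `p x p` row covariance.
#' @param V symmetric positive definite `q x q` column covariance.
#' @return An object of class `matnorm_params` with elements `M`, `U`, `V`.
#' @examples
#' matnorm_params(matrix(0, 2, 3), diag(2), diag(3))
#' @export
matnorm_params <- function(M, U, V) {
  M <- as.matrix(M)
  check_spd(U, "U")
  check_spd(V, "V")
  if (nrow(U) != nrow(M) || nrow(V) != ncol(M))
    stop(sprintf("dimension mismatch: M is %dx%d but U is %dx%d and V is %dx%d",
                 nrow(M), ncol(M), nrow(U), ncol(U), nrow(V), ncol(V)))
  structure(list(M = M, U = as.matrix(U), V = as.matrix(V)),
            class = "matnorm_params")
}

#' @export
print.matnorm_params <- function(x, ...) {
  cat(sprintf("matnorm_params: p = %d, q = %d, trace(U) = %.4g\n",
              nrow(x$M), ncol(x$M), sum(diag(x$U))))
  invisible(x)
}

# Symmetry within 1e-10 and positive definiteness (via Cholesky).
check_spd <- function(A, name) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop(sprintf("%s must be square", name))
  if (max(abs(A - t(A))) > 1e-10 * max(1, max(abs(A))))
    stop(sprintf("%s is not symmetric", name))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("%s is not positive definite", name))
  invisible(ch)
}

#' Matrix normal log-density
#'
#' Evaluates the log of the matrix normal density
#' \deqn{f(X) = (2\pi)^{-pq/2} |V|^{-p/2} |U|^{-q/2}
#'   \exp\{-\tfrac12 \mathrm{tr}(V^{-1}(X-M)^\top U^{-1}(X-M))\}}
#' through Cholesky factorizations of `U` and `V`; the `pq x pq` Kronecker
#' covariance is never formed.
#'
#' @param X a `p x q` matrix, or a stack of them (see
#'   [as_matrix_samples()]); with a stack, one value per sample is returned.
#' @param params a [matnorm_params()] object.
#' @return Numeric vector of log-density values.
#' @examples
#' pr <- matnorm_params(matrix(0, 2, 2), diag(2), diag(2))
#' matnorm_logpdf(diag(2), pr)  # -2*log(2*pi) - 1
#' @export
matnorm_logpdf <- function(X, params) {
  stopifnot(inherits(params, "matnorm_params"))
  if (is.matrix(X)) X <- array(X, dim = c(nrow(X), ncol(X), 1L))
  X <- as_matrix_samples(X)
  d <- sample_dims(X)
  if (d$p != nrow(params$M) || d$q != ncol(params$M))
    stop(sprintf("X is %dx%d but the mean matrix is %dx%d",
                 d$p, d$q, nrow(params$M), ncol(params$M)))
  check_spd(params$U, "U")
  check_spd(params$V, "V")
  as.numeric(cpp_matnorm_logpdf(unclass(X), params$M, params$U, params$V))
}

#' Sample from a matrix normal distribution
#'
#' Draws `n` matrices via \eqn{X = M + A Z B^\top} with \eqn{AA^\top = U},
#' \eqn{BB^\top = V} (Cholesky factors) and `Z` a matrix of i.i.d. standard
#' normals.
#'
#' @param params a [matnorm_params()] object.
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return A [as_matrix_samples()] stack of `n` draws.
#' @export
sample_matnorm <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "matnorm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(params$M); q <- ncol(params$M)
  A <- t(check_spd(params$U, "U"))  # lower factor
  B <- t(check_spd(params$V, "V"))
  out <- array(0, dim = c(p, q, n))
  for (i in seq_len(n)) {
    Z <- matrix(stats::rnorm(p * q), p, q)
    out[, , i] <- params$M + A %*% Z %*% t(B)
  }
  as_matrix_samples(out)
}

#' Maximum likelihood estimation for the matrix normal
#'
#' Flip-flop estimation: the mean is the sample mean; `U` and `V` are
#' obtained by alternating their closed-form updates
#' \deqn{\hat U = \frac{1}{nq}\sum_i (X_i-\bar X)\hat V^{-1}(X_i-\bar X)^\top,
#' \quad
#' \hat V = \frac{1}{np}\sum_i (X_i-\bar X)^\top\hat U^{-1}(X_i-\bar X)}
#' (the `U` update first, with the current `V`) until the relative
#' Frobenius change of both factors falls below `tol`.  The returned pair
#' is passed through [normalize_scale()] so that `trace(U) = p`.
#'
#' @param samples a sample stack (see [as_matrix_samples()]).
#' @param tol relative Frobenius convergence tolerance (default 0.01).
#' @param max_iter maximum number of flip-flop sweeps.
#' @return A [matnorm_params()] object.
#' @export
fit_matnorm_mle <- function(samples, tol = 0.01, max_iter = 100) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  M <- apply(unclass(samples), c(1, 2), mean)
  res <- cpp_flipflop(unclass(samples), M, tol, as.integer(max_iter))
  if (res$status == 1L)
    stop(sprintf(paste0("rank-deficient scatter matrix in flip-flop ",
                        "estimation (n = %d, p = %d, q = %d): increase the ",
                        "sample size or add a ridge"), d$n, d$p, d$q))
  if (res$status == 2L)
    stop(structure(class = c("pmnmm_nonconvergence", "error", "condition"),
                   list(message = sprintf(
                     "flip-flop did not converge in %d iterations", max_iter),
                     call = sys.call(), last = res)))
  uv <- normalize_scale(res$U, res$V)
  matnorm_params(M, uv$U, uv$V)
}

#' Fix the scale indeterminacy of a Kronecker covariance pair
#'
#' Only the product \eqn{V \otimes U} is identified: `(cU, V/c)` describes
#' the same distribution for any `c > 0`.  This returns the representative
#' with `trace(U) = p`, leaving the Kronecker product unchanged.
#'
#' @param U,V symmetric positive definite matrices.
#' @return A list with rescaled elements `U` and `V`.
#' @examples
#' normalize_scale(2 * diag(3), diag(2))  # U -> I3, V -> 2*I2
#' @export
normalize_scale <- function(U, V) {
  check_spd(U, "U")
  check_spd(V, "V")
  cc <- nrow(U) / sum(diag(U))
  list(U = cc * U, V = V / cc)
}
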