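#' Penalized precision estimation (graphical lasso)
#'
#' Maximizes \deqn{\log|\Theta| - \mathrm{tr}(S\Theta) - \rho |\Theta|_1}
#' over symmetric positive definite matrices, where \eqn{|\Theta|_1} sums
#' the absolute values of all entries (the diagonal is penalized by
#' default).  The problem is solved by ADMM with eigenvalue shrinkage in
#' the smooth block and elementwise soft thresholding in the sparse block;
#' first-order (KKT) optimality of the returned solution is verified and
#' enforced to `kkt_tol`:
#' \itemize{
#'   \item nonzero entries: \eqn{(\Theta^{-1})_{ij} = S_{ij} +
#'     \rho\,\mathrm{sign}(\Theta_{ij})} within `kkt_tol`;
#'   \item zero entries: \eqn{|(\Theta^{-1})_{ij} - S_{ij}| \le \rho +}
#'     `kkt_tol`.
#' }
#' With `rho = 0` the unpenalized maximizer \eqn{S^{-1}} is returned.
#'
#' @param S symmetric positive semidefinite input matrix (a scatter or
#'   covariance estimate).
#' @param rho nonnegative L1 penalty.
#' @param penalize_diagonal should the diagonal be included in the penalty?
#'   Default `TRUE`.
#' @param kkt_tol maximum admissible KKT residual (default `1e-4`).
#' @param max_iter ADMM iteration cap per attempt.
#' @param warm_start optional symmetric matrix used to initialize the
#'   sparse block (e.g. the previous EM iterate).
#' @return A symmetric positive definite precision matrix whose zero
#'   pattern is exact, with attribute `"kkt_residual"`.
#' @seealso [glasso_kkt_residual()]
#' @export
solve_penalized_precision <- function(S, rho, penalize_diagonal = TRUE,
                                      kkt_tol = 1e-4, max_iter = 2000L,
                                      warm_start = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  if (rho < 0) stop("rho must be nonnegative")
  if (rho == 0) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("rho = 0 requires a positive definite S (singular scatter)")
    Theta <- chol2inv(ch)
    Theta <- (Theta + t(Theta)) / 2
    attr(Theta, "kkt_residual") <- glasso_kkt_residual(Theta, S, 0)
    return(Theta)
  }
  tol <- 1e-6 * max(1, norm(S, "F"))
  for (attempt in 1:3) {
    res <- cpp_glasso_admm(S, rho, penalize_diagonal, tol,
                           as.integer(max_iter), warm_start)
    Theta <- pick_glasso_iterate(res)
    kkt <- glasso_kkt_residual(Theta, S, rho,
                               penalize_diagonal = penalize_diagonal)
    if (kkt <= kkt_tol) {
      attr(Theta, "kkt_residual") <- kkt
      return(Theta)
    }
    tol <- tol / 100
    max_iter <- max_iter * 4L
    warm_start <- res$Z
  }
  stop(structure(class = c("pmnmm_nonconvergence", "error", "condition"),
                 list(message = sprintf(
                   "graphical lasso did not reach KKT tolerance (residual %.3g > %.3g)",
                   kkt, kkt_tol), call = sys.call(), last = res)))
}

# Prefer the thresholded iterate (exact zeros) when it is positive
# definite; otherwise the smooth iterate, which always is.
pick_glasso_iterate <- function(res) {
  Z <- (res$Z + t(res$Z)) / 2
  if (!is.null(tryCatch(chol(Z), error = function(e) NULL))) return(Z)
  (res$Theta + t(res$Theta)) / 2
}

#' KKT residual of a graphical lasso solution
#'
#' Largest violation of the stationarity conditions of the penalized
#' log-determinant problem (see [solve_penalized_precision()]).
#'
#' @param Theta candidate precision matrix.
#' @param S the input matrix of the solve.
#' @param rho the L1 penalty used.
#' @param penalize_diagonal whether the diagonal was penalized.
#' @return The maximum absolute residual (scalar).
#' @export
glasso_kkt_residual <- function(Theta, S, rho, penalize_diagonal = TRUE) {
  W <- chol2inv(chol(Theta))          # Theta^{-1}
  R <- W - S
  nz <- Theta != 0
  if (!penalize_diagonal) diag(nz) <- TRUE  # diagonal: unpenalized stationarity
  rho_eff <- matrix(rho, nrow(S), ncol(S))
  if (!penalize_diagonal) diag(rho_eff) <- 0
  res_nz <- abs(R - rho_eff * sign(Theta))[nz]
  res_z <- pmax(abs(R) - rho_eff, 0)[!nz]
  max(c(res_nz, res_z, 0))
}
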