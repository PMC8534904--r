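#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Cholesky with a descriptive failure flag instead of an exception.
static bool chol_lower(mat &L, const mat &A) {
  return chol(L, symmatu(A), "lower");
}

static double logdet_from_chol(const mat &L) {
  return 2.0 * accu(log(L.diag()));
}

// Log-density of each slice of X under the matrix normal N_{p,q}(M, U, V).
// Computed through Cholesky factors of U and V: the quadratic form
// tr(V^{-1}(X-M)' U^{-1} (X-M)) equals ||L_U^{-1} (X-M) L_V^{-T}||_F^2.
// [[Rcpp::export]]
arma::vec cpp_matnorm_logpdf(const arma::cube &X, const arma::mat &M,
                             const arma::mat &U, const arma::mat &V) {
  const uword p = M.n_rows, q = M.n_cols, n = X.n_slices;
  mat LU, LV;
  if (!chol_lower(LU, U)) Rcpp::stop("row covariance U is not positive definite");
  if (!chol_lower(LV, V)) Rcpp::stop("column covariance V is not positive definite");
  const double ldU = logdet_from_chol(LU), ldV = logdet_from_chol(LV);
  const double cst = -0.5 * (double)(p * q) * std::log(2.0 * datum::pi)
                     - 0.5 * (double)p * ldV - 0.5 * (double)q * ldU;
  vec out(n);
  for (uword i = 0; i < n; ++i) {
    mat A = solve(trimatl(LU), X.slice(i) - M);
    mat B = solve(trimatl(LV), A.t());
    out(i) = cst - 0.5 * accu(square(B));
  }
  return out;
}

// Weighted, whitened row scatter (Eq. for the row factor):
//   sum_i tau_i (X_i - M) Winv (X_i - M)' / (q * sum_i tau_i)
// When byrow = false the transposed (column-factor) version with divisor p
// is returned. Output symmetrized to remove roundoff skew.
// [[Rcpp::export]]
arma::mat cpp_weighted_scatter(const arma::cube &X, const arma::vec &tau,
                               const arma::mat &M, const arma::mat &Winv,
                               const bool byrow) {
  const uword p = M.n_rows, q = M.n_cols, n = X.n_slices;
  const double tsum = accu(tau);
  mat S = byrow ? mat(p, p, fill::zeros) : mat(q, q, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    if (tau(i) == 0.0) continue;
    mat E = X.slice(i) - M;
    if (byrow)
      S += tau(i) * (E * Winv * E.t());
    else
      S += tau(i) * (E.t() * Winv * E);
  }
  const double div = (byrow ? (double)q : (double)p) * tsum;
  S /= div;
  return symmatu(0.5 * (S + S.t()));
}

// Flip-flop maximum likelihood for a single matrix normal: alternate the
// closed-form updates of U given V and V given U until both relative
// Frobenius changes fall below tol.  Returns status 0 on convergence,
// 1 when an intermediate scatter is rank deficient, 2 when max_iter is hit.
// [[Rcpp::export]]
Rcpp::List cpp_flipflop(const arma::cube &X, const arma::mat &M,
                        const double tol, const int max_iter) {
  const uword p = M.n_rows, q = M.n_cols, n = X.n_slices;
  vec tau(n, fill::ones);
  mat U = eye(p, p), V = eye(q, q), LV, LU;
  int status = 2, iters = 0;
  for (int t = 0; t < max_iter; ++t) {
    ++iters;
    if (!chol_lower(LV, V)) { status = 1; break; }
    mat Vinv = inv_sympd(symmatu(V));
    mat Unew = cpp_weighted_scatter(X, tau, M, Vinv, true);
    // divisor in the single-sample MLE is nq: tau sums to n already
    if (!chol_lower(LU, Unew)) { status = 1; break; }
    mat Uinv = inv_sympd(symmatu(Unew));
    mat Vnew = cpp_weighted_scatter(X, tau, M, Uinv, false);
    if (!chol_lower(LV, Vnew)) { status = 1; break; }
    const double du = norm(U - Unew, "fro") / std::max(norm(U, "fro"), 1e-300);
    const double dv = norm(V - Vnew, "fro") / std::max(norm(V, "fro"), 1e-300);
    U = Unew; V = Vnew;
    if (du < tol && dv < tol) { status = 0; break; }
  }
  return Rcpp::List::create(Rcpp::Named("U") = U, Rcpp::Named("V") = V,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("status") = status);
}

// Graphical lasso by ADMM:
//   maximize log det(Theta) - tr(S Theta) - rho * |Theta|_1
// over symmetric positive definite Theta, with the L1 penalty on every
// entry (diagonal included) unless penalize_diagonal is false.
// Splitting Theta = Z: the Theta update is an eigenvalue shrinkage, the Z
// update an elementwise soft threshold; the scaled dual is adapted so the
// primal and dual residuals stay balanced.  Returns both the smooth iterate
// (positive definite by construction) and the thresholded iterate Z
// (carrying the exact zero pattern).
// [[Rcpp::export]]
Rcpp::List cpp_glasso_admm(const arma::mat &S, const double rho,
                           const bool penalize_diagonal,
                           const double tol, const int max_iter,
                           Rcpp::Nullable<Rcpp::NumericMatrix> Z_init = R_NilValue) {
  const uword d = S.n_rows;
  mat Z;
  if (Z_init.isNotNull()) {
    Z = Rcpp::as<arma::mat>(Z_init.get());
  } else {
    vec dg = 1.0 / (S.diag() + rho);
    Z = diagmat(dg);
  }
  mat Udual(d, d, fill::zeros), Theta(d, d, fill::zeros);
  double mu = 1.0;
  bool converged = false;
  int iters = 0;
  vec eval;
  mat evec;
  for (int t = 0; t < max_iter; ++t) {
    ++iters;
    // Theta step: argmax log det(Theta) - tr(S Theta) - (mu/2)||Theta - Z + Udual||_F^2
    if (!eig_sym(eval, evec, symmatu(mu * (Z - Udual) - S)))
      Rcpp::stop("eigendecomposition failed in the graphical lasso solver");
    vec thv = (eval + sqrt(square(eval) + 4.0 * mu)) / (2.0 * mu);
    Theta = evec * diagmat(thv) * evec.t();
    Theta = symmatu(0.5 * (Theta + Theta.t()));
    // Z step: soft threshold
    mat Zold = Z;
    mat T = Theta + Udual;
    Z = sign(T) % max(abs(T) - rho / mu, zeros<mat>(d, d));
    if (!penalize_diagonal) Z.diag() = T.diag();
    Udual += Theta - Z;
    const double rpri = norm(Theta - Z, "fro");
    const double rdua = mu * norm(Z - Zold, "fro");
    if (rpri < tol && rdua < tol) { converged = true; break; }
    if (rpri > 10.0 * rdua) { mu *= 2.0; Udual /= 2.0; }
    else if (rdua > 10.0 * rpri) { mu /= 2.0; Udual *= 2.0; }
  }
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta, Rcpp::Named("Z") = Z,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = converged);
}

// Weighted component mean sum_i tau_i X_i / sum_i tau_i.
// [[Rcpp::export]]
arma::mat cpp_weighted_mean(const arma::cube &X, const arma::vec &tau) {
  const uword n = X.n_slices;
  const double tsum = accu(tau);
  mat M(X.n_rows, X.n_cols, fill::zeros);
  for (uword i = 0; i < n; ++i) M += tau(i) * X.slice(i);
  return M / tsum;
}
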