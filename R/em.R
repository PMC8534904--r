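#' Penalty configuration
#'
#' The three lasso tuning parameters of the penalized matrix normal
#' mixture: `lambda1` shrinks the component mean matrices elementwise,
#' `lambda2` and `lambda3` shrink the row and column precision matrices
#' (\eqn{U^{-1}}, \eqn{V^{-1}}) through graphical lasso solves.  All three
#' set to zero reproduces the unpenalized matrix normal mixture.
#'
#' @param lambda1,lambda2,lambda3 nonnegative reals.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0) {
  lam <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("penalties must be finite and nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "penalty_config")
}

# One mixture component: mean, covariance factors and their inverses.
new_component <- function(M, U, V, Uinv = NULL, Vinv = NULL) {
  if (is.null(Uinv)) Uinv <- chol2inv(chol(U))
  if (is.null(Vinv)) Vinv <- chol2inv(chol(V))
  list(M = M, U = (U + t(U)) / 2, V = (V + t(V)) / 2,
       Uinv = (Uinv + t(Uinv)) / 2, Vinv = (Vinv + t(Vinv)) / 2)
}

new_mixture_model <- function(weights, components, penalties, trace = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, length(weights) == length(components))
  structure(list(G = length(weights), weights = as.numeric(weights),
                 components = components, penalties = penalties,
                 trace = trace),
            class = "pmnmm_model")
}

#' @export
print.pmnmm_model <- function(x, ...) {
  p <- nrow(x$components[[1]]$M); q <- ncol(x$components[[1]]$M)
  cat(sprintf("Penalized matrix normal mixture: G = %d components, %d x %d matrices\n",
              x$G, p, q))
  cat(sprintf("  weights: %s\n", paste(signif(x$weights, 4), collapse = ", ")))
  cat(sprintf("  penalties: lambda1 = %g, lambda2 = %g, lambda3 = %g\n",
              x$penalties$lambda1, x$penalties$lambda2, x$penalties$lambda3))
  if (!is.null(x$trace))
    cat(sprintf("  EM: %d iterations, converged = %s, penalized loglik = %.4f\n",
                x$trace$n_iter, x$trace$converged,
                x$trace$loglik_history[x$trace$n_iter]))
  invisible(x)
}

# n x G matrix of log(pi_j) + log f(X_i | component j).
component_logdens <- function(samples, model) {
  samples <- as_matrix_samples(samples)
  ld <- vapply(seq_len(model$G), function(j) {
    cmp <- model$components[[j]]
    as.numeric(cpp_matnorm_logpdf(unclass(samples), cmp$M, cmp$U, cmp$V)) +
      log(model$weights[j])
  }, numeric(dim(samples)[3]))
  matrix(ld, ncol = model$G)
}

#' E-step: posterior membership probabilities
#'
#' Computes the responsibilities
#' \eqn{\tau_{ij} \propto \pi_j f(X_i \mid \Theta_j)}, evaluated in log
#' space with per-row maximum subtraction so that large `p x q` matrices do
#' not underflow; each row is normalized to sum to one.
#'
#' @param samples a sample stack.
#' @param model a fitted or initialized mixture model.
#' @return An `n x G` matrix of responsibilities.
#' @export
e_step <- function(samples, model) {
  ld <- component_logdens(samples, model)
  mx <- apply(ld, 1, max)
  if (any(!is.finite(mx)))
    stop(sprintf("all component densities vanish for sample %d",
                 which(!is.finite(mx))[1]))
  w <- exp(ld - mx)
  w <- pmax(w, 1e-300)
  tau <- w / rowSums(w)
  tau
}

#' M-step: mixing weights
#'
#' @param tau an `n x G` responsibility matrix (see [e_step()]).
#' @return The updated weight vector, the column means of `tau`.
#' @export
update_weights <- function(tau) {
  colMeans(tau)
}

#' M-step: penalized mean update
#'
#' For each component the responsibility-weighted mean
#' \eqn{\hat M_j = \sum_i \tau_{ij} X_i / \sum_i \tau_{ij}} is shrunk
#' elementwise by soft thresholding at the matrix threshold
#' \deqn{T_j = \frac{\lambda_1}{\sum_i \tau_{ij}}\, U_j \mathbf{1}_{p\times q} V_j,}
#' i.e. the update is \eqn{\mathrm{sign}(\hat M_j)\max(|\hat M_j| - T_j, 0)}.
#' `U_j`, `V_j` are the current (pre-update) covariance factors.  Entries of
#' \eqn{T_j} that come out negative (possible when `U` or `V` has negative
#' off-diagonal row/column sums) carry no meaningful shrinkage and are
#' clamped to zero.
#'
#' @param samples a sample stack.
#' @param tau responsibility matrix.
#' @param model current mixture model (supplies `U_j`, `V_j`).
#' @param lambda1 nonnegative mean penalty.
#' @return A list of `G` updated mean matrices.
#' @export
update_means_penalized <- function(samples, tau, model, lambda1) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  tsum <- colSums(tau)
  if (any(tsum <= 0))
    stop(structure(class = c("pmnmm_empty_cluster", "error", "condition"),
                   list(message = sprintf("component %d has no effective samples",
                                          which(tsum <= 0)[1]),
                        call = sys.call())))
  ones <- matrix(1, d$p, d$q)
  lapply(seq_len(model$G), function(j) {
    cmp <- model$components[[j]]
    Mhat <- cpp_weighted_mean(unclass(samples), tau[, j])
    if (lambda1 == 0) return(Mhat)
    Tj <- (lambda1 / tsum[j]) * (cmp$U %*% ones %*% cmp$V)
    Tj[Tj < 0] <- 0
    sign(Mhat) * pmax(abs(Mhat) - Tj, 0)
  })
}

#' Weighted whitened scatter matrices
#'
#' Building blocks of the precision updates: the row scatter
#' \deqn{\tilde S_j^{(U)} = \frac{\sum_i \tau_{ij} (X_i - M_j) V_j^{-1}
#'   (X_i - M_j)^\top}{q \sum_i \tau_{ij}}}
#' and its column counterpart with the roles of rows and columns exchanged
#' and divisor `p`.  Outputs are symmetrized to remove roundoff skew.
#'
#' @param samples a sample stack.
#' @param tau_col length-`n` vector of responsibilities for one component.
#' @param M the component mean matrix.
#' @param V_inv,U_inv the whitening precision factor of the opposite side.
#' @return A symmetric `p x p` (resp. `q x q`) scatter matrix.
#' @export
weighted_scatter_U <- function(samples, tau_col, M, V_inv) {
  samples <- as_matrix_samples(samples)
  if (sum(tau_col) <= 0) stop("responsibilities sum to zero")
  cpp_weighted_scatter(unclass(samples), as.numeric(tau_col), M, V_inv, TRUE)
}

#' @rdname weighted_scatter_U
#' @export
weighted_scatter_V <- function(samples, tau_col, M, U_inv) {
  samples <- as_matrix_samples(samples)
  if (sum(tau_col) <= 0) stop("responsibilities sum to zero")
  cpp_weighted_scatter(unclass(samples), as.numeric(tau_col), M, U_inv, FALSE)
}

#' M-step: penalized precision updates
#'
#' For each component, first the row precision \eqn{U_j^{-1}} is the
#' graphical lasso solution at input \eqn{\tilde S_j^{(U)}} (built with the
#' current \eqn{V_j^{-1}}) and penalty
#' \eqn{\rho = 2\lambda_2 / (q \sum_i \tau_{ij})}; then the column
#' precision \eqn{V_j^{-1}} is solved at \eqn{\tilde S_j^{(V)}} built with
#' the freshly updated \eqn{U_j^{-1}} and penalty
#' \eqn{\rho = 2\lambda_3 / (p \sum_i \tau_{ij})}.  With
#' `normalize = TRUE` each returned pair is rescaled so `trace(U) = p`.
#' During EM iterations [fit_pmnmm()] keeps the solver-chosen scale
#' instead (`normalize = FALSE`), because the L1 penalties break the scale
#' indeterminacy and rescaling mid-iteration would move off the optimum of
#' the M-step surrogate; the final model is normalized once at return.
#'
#' @param samples a sample stack.
#' @param tau responsibility matrix.
#' @param model current mixture model (supplies the whitening factors).
#' @param lambda2,lambda3 nonnegative precision penalties.
#' @param means optional list of already-updated mean matrices (defaults to
#'   the model's current means).
#' @param normalize apply [normalize_scale()] to each pair (default TRUE).
#' @return A list of `G` lists with elements `U`, `V`, `Uinv`, `Vinv`.
#' @export
update_precisions <- function(samples, tau, model, lambda2, lambda3,
                              means = NULL, normalize = TRUE) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  tsum <- colSums(tau)
  if (any(tsum <= 0))
    stop(structure(class = c("pmnmm_empty_cluster", "error", "condition"),
                   list(message = sprintf("component %d has no effective samples",
                                          which(tsum <= 0)[1]),
                        call = sys.call())))
  if (is.null(means)) means <- lapply(model$components, `[[`, "M")
  lapply(seq_len(model$G), function(j) {
    cmp <- model$components[[j]]
    SU <- weighted_scatter_U(samples, tau[, j], means[[j]], cmp$Vinv)
    rhoU <- 2 * lambda2 / (d$q * tsum[j])
    Uinv <- solve_penalized_precision(SU, rhoU, warm_start = cmp$Uinv)
    U <- chol2inv(chol(Uinv))
    SV <- weighted_scatter_V(samples, tau[, j], means[[j]], Uinv)
    rhoV <- 2 * lambda3 / (d$p * tsum[j])
    Vinv <- solve_penalized_precision(SV, rhoV, warm_start = cmp$Vinv)
    V <- chol2inv(chol(Vinv))
    if (normalize) {
      cc <- d$p / sum(diag(U))
      U <- cc * U; Uinv <- Uinv / cc
      V <- V / cc; Vinv <- cc * Vinv
    }
    list(U = (U + t(U)) / 2, V = (V + t(V)) / 2,
         Uinv = (Uinv + t(Uinv)) / 2, Vinv = (Vinv + t(Vinv)) / 2)
  })
}

#' Penalized mixture log-likelihood
#'
#' The observed-data mixture log-likelihood
#' \eqn{\sum_i \log \sum_j \pi_j f(X_i \mid \Theta_j)} (evaluated by
#' log-sum-exp) minus the three L1 penalty terms
#' \eqn{\lambda_1 \sum_j |M_j|_1 + \lambda_2 \sum_j |U_j^{-1}|_1 +
#' \lambda_3 \sum_j |V_j^{-1}|_1}, where \eqn{|\cdot|_1} sums the absolute
#' values of all entries.  With all penalties zero this is the plain
#' mixture log-likelihood.
#'
#' @param samples a sample stack.
#' @param model a mixture model carrying its `penalty_config`.
#' @return A scalar.
#' @export
penalized_loglik <- function(samples, model) {
  ld <- component_logdens(samples, model)
  mx <- apply(ld, 1, max)
  ll <- sum(mx + log(rowSums(exp(ld - mx))))
  pen <- model$penalties
  l1 <- sum(vapply(model$components, function(c) sum(abs(c$M)), 0))
  l2 <- sum(vapply(model$components, function(c) sum(abs(c$Uinv)), 0))
  l3 <- sum(vapply(model$components, function(c) sum(abs(c$Vinv)), 0))
  ll - pen$lambda1 * l1 - pen$lambda2 * l2 - pen$lambda3 * l3
}

#' Aitken-accelerated stopping rule
#'
#' From the last three penalized log-likelihood values the acceleration
#' ratio \eqn{a^{(t)} = (l^{(t)} - l^{(t-1)}) / (l^{(t-1)} - l^{(t-2)})}
#' and the accelerated limit estimate
#' \eqn{\hat l^{(t)} = l^{(t-1)} + (l^{(t)} - l^{(t-1)}) / (1 - a^{(t)})}
#' are formed; iteration stops when
#' \eqn{0 \le (\hat l^{(t)} - l^{(t)}) / |l^{(t)}| \le \epsilon}.
#' Degenerate cases: histories shorter than 3 continue; a zero denominator
#' in \eqn{a^{(t)}} (flat likelihood) stops; \eqn{a^{(t)} \ge 1} falls back
#' to the plain relative change criterion
#' \eqn{|l^{(t)} - l^{(t-1)}| / |l^{(t)}| \le \epsilon}.
#'
#' @param loglik_history numeric vector of penalized log-likelihood values.
#' @param epsilon positive stopping tolerance (default 0.001).
#' @return A list with elements `stop` (logical) and `accelerated` (the
#'   accelerated value, `NA` when not computable).
#' @export
aitken_should_stop <- function(loglik_history, epsilon = 0.001) {
  t <- length(loglik_history)
  if (t < 3) return(list(stop = FALSE, accelerated = NA_real_))
  l2 <- loglik_history[t - 2]; l1 <- loglik_history[t - 1]
  l0 <- loglik_history[t]
  den <- l1 - l2
  if (den == 0) {
    return(list(stop = TRUE, accelerated = l0))
  }
  a <- (l0 - l1) / den
  if (a >= 1) {
    rel <- abs(l0 - l1) / abs(l0)
    return(list(stop = rel <= epsilon, accelerated = NA_real_))
  }
  acc <- l1 + (l0 - l1) / (1 - a)
  crit <- (acc - l0) / abs(l0)
  list(stop = crit >= 0 && crit <= epsilon, accelerated = acc)
}

#' K-means initialization of the mixture
#'
#' Vectorized samples are partitioned into `G` clusters with K-means; the
#' matrix normal MLE ([fit_matnorm_mle()]) is computed within each cluster
#' and the mixing weights are the cluster proportions.  Clusters too small
#' (or too degenerate) for the flip-flop MLE fall back to a ridge
#' initialization: the cluster mean with identity covariance factors scaled
#' to the cluster variance.
#'
#' @param samples a sample stack.
#' @param G number of components.
#' @param seed integer seed making the K-means start reproducible.
#' @return An initialized `pmnmm_model` with zero penalties.
#' @export
init_kmeans <- function(samples, G, seed = NULL) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  if (d$n < G) stop(sprintf("need at least G = %d samples, got %d", G, d$n))
  if (!is.null(seed)) set.seed(seed)
  vd <- vectorize_samples(samples)
  cl <- if (G == 1) rep(1L, d$n) else
    stats::kmeans(vd, centers = G, nstart = 5, iter.max = 50)$cluster
  components <- lapply(seq_len(G), function(j) {
    idx <- which(cl == j)
    sub <- subset_samples(samples, idx)
    fit <- tryCatch(fit_matnorm_mle(sub), error = function(e) NULL)
    if (!is.null(fit))
      return(new_component(fit$M, fit$U, fit$V))
    # ridge fallback for clusters too small for the flip-flop MLE
    M <- apply(unclass(sub), c(1, 2), mean)
    v <- max(stats::var(as.numeric(sweep_means(sub, M))), 1e-8)
    uv <- normalize_scale(sqrt(v) * diag(d$p), sqrt(v) * diag(d$q))
    new_component(M, uv$U, uv$V)
  })
  w <- tabulate(cl, nbins = G) / d$n
  new_mixture_model(w, components, penalty_config(0, 0, 0))
}

# Residuals X_i - M for every slice (helper for the ridge fallback).
sweep_means <- function(samples, M) {
  unclass(samples) - array(M, dim = dim(samples))
}

#' Fit a penalized matrix normal mixture model
#'
#' The full EM procedure: K-means initialization ([init_kmeans()]), then
#' iterations of E-step, weight update, penalized mean update
#' ([update_means_penalized()]), graphical-lasso precision updates
#' ([update_precisions()]) and the Aitken-accelerated stopping rule
#' ([aitken_should_stop()]) on the penalized log-likelihood.  Because the
#' penalized likelihood surface is multimodal the algorithm is restarted
#' `n_restarts` times from different K-means initializations and the
#' restart with the highest final penalized log-likelihood is returned.
#' Restarts that collapse a component below `max(p, q) + 1` effective
#' samples are abandoned (the scatter matrices would be rank deficient).
#'
#' @param samples a sample stack (see [as_matrix_samples()]).
#' @param G number of mixture components.
#' @param penalties a [penalty_config()].
#' @param n_restarts number of EM restarts (default 5).
#' @param seed master integer seed; all restart seeds derive from it.
#' @param epsilon Aitken stopping tolerance (default 0.001).
#' @param max_iter EM iteration cap per restart (default 200).
#' @param verbose print per-restart progress.
#' @return A `pmnmm_model` whose `trace` element records the penalized
#'   log-likelihood history, the Aitken history, the iteration count,
#'   convergence flag and winning restart index.  The returned covariance
#'   factors are normalized to `trace(U) = p`.
#' @examples
#' \donttest{
#' spec <- scenario_spec(1, n = 60, p = 8, q = 8, seed = 1)
#' xs <- sample_scenario(spec)
#' fit <- fit_pmnmm(xs$samples, G = 2, penalty_config(1, 0.01, 0.01),
#'                  n_restarts = 2, seed = 1)
#' table(xs$labels, predict_labels(xs$samples, fit))
#' }
#' @export
fit_pmnmm <- function(samples, G, penalties = penalty_config(),
                      n_restarts = 5, seed = NULL, epsilon = 0.001,
                      max_iter = 200, verbose = FALSE) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  if (d$n < G) stop(sprintf("need at least G = %d samples, got %d", G, d$n))
  stopifnot(inherits(penalties, "penalty_config"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)
  rseeds <- sample.int(1e9, n_restarts)
  floor_n <- max(d$p, d$q) + 1
  best <- NULL
  failures <- character(0)
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      em_single_run(samples, G, penalties, rseeds[r], epsilon, max_iter,
                    floor_n, restart_index = r),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("restart %d: %s", r, conditionMessage(fit)))
      next
    }
    if (verbose)
      message(sprintf("restart %d: %d iterations, penalized loglik %.4f",
                      r, fit$trace$n_iter, fit$trace$final_loglik))
    if (is.null(best) || fit$trace$final_loglik > best$trace$final_loglik)
      best <- fit
  }
  if (is.null(best))
    stop(sprintf("all %d restarts failed:\n%s", n_restarts,
                 paste(failures, collapse = "\n")))
  best$trace$n_failed_restarts <- length(failures)
  # fix the scale representative once, at return
  best$components <- lapply(best$components, function(cmp) {
    cc <- d$p / sum(diag(cmp$U))
    new_component(cmp$M, cc * cmp$U, cmp$V / cc,
                  cmp$Uinv / cc, cc * cmp$Vinv)
  })
  best
}

em_single_run <- function(samples, G, penalties, seed, epsilon, max_iter,
                          floor_n, restart_index) {
  model <- init_kmeans(samples, G, seed)
  model$penalties <- penalties
  history <- numeric(0)
  aitken <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    tau <- e_step(samples, model)
    tsum <- colSums(tau)
    if (any(tsum < floor_n))
      stop(structure(class = c("pmnmm_empty_cluster", "error", "condition"),
                     list(message = sprintf(
                       "component %d collapsed (%.2f effective samples < %d)",
                       which.min(tsum), min(tsum), floor_n),
                       call = sys.call())))
    w <- update_weights(tau)
    means <- update_means_penalized(samples, tau, model, penalties$lambda1)
    prec <- update_precisions(samples, tau, model, penalties$lambda2,
                              penalties$lambda3, means = means,
                              normalize = FALSE)
    model <- new_mixture_model(w, lapply(seq_len(G), function(j)
      new_component(means[[j]], prec[[j]]$U, prec[[j]]$V,
                    prec[[j]]$Uinv, prec[[j]]$Vinv)),
      penalties)
    history <- c(history, penalized_loglik(samples, model))
    st <- aitken_should_stop(history, epsilon)
    aitken <- c(aitken, if (is.na(st$accelerated)) NA_real_ else st$accelerated)
    if (st$stop) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  model$trace <- list(loglik_history = history, aitken_history = aitken,
                      n_iter = iter, converged = converged,
                      restart_index = restart_index,
                      final_loglik = history[length(history)])
  model
}

#' MAP cluster assignment
#'
#' Assigns each sample to the component with the largest posterior
#' membership probability; ties break toward the lower component index.
#'
#' @param samples a sample stack.
#' @param model a fitted `pmnmm_model`.
#' @return An integer vector of labels in `1..G`, with the responsibility
#'   matrix attached as attribute `"responsibilities"`.
#' @export
predict_labels <- function(samples, model) {
  tau <- e_step(samples, model)
  labels <- max.col(tau, ties.method = "first")
  attr(labels, "responsibilities") <- tau
  labels
}
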