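#' Clustering accuracy under optimal label matching
#'
#' The fraction of agreements between two labelings, maximized over all
#' one-to-one matchings of predicted to true cluster codes (exact optimal
#' assignment on the confusion matrix; cluster codes may be arbitrary
#' integers).  For two clusters this reduces to
#' `max(agreement, 1 - agreement)`.
#'
#' @param truth,pred equal-length label vectors.
#' @return A number in `[1/G, 1]`.
#' @examples
#' clustering_accuracy(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1
#' @export
clustering_accuracy <- function(truth, pred) {
  ct <- confusion_table(truth, pred)
  n <- sum(ct)
  best_assignment_trace(ct) / n
}

confusion_table <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(truth), length(pred)))
  lt <- sort(unique(truth)); lp <- sort(unique(pred))
  k <- max(length(lt), length(lp))
  ct <- matrix(0, k, k)
  tab <- table(factor(truth, levels = lt), factor(pred, levels = lp))
  ct[seq_along(lt), seq_along(lp)] <- tab
  ct
}

# Exact optimal assignment by enumeration (cluster counts are small in
# this setting; G! is tiny for G <= 8).
best_assignment_trace <- function(ct) {
  res <- best_assignment(ct)
  res$value
}

best_assignment <- function(ct) {
  k <- nrow(ct)
  if (k > 8)
    stop("optimal matching by enumeration supports at most 8 clusters")
  perms <- all_permutations(k)
  vals <- vapply(perms, function(pp) sum(ct[cbind(seq_len(k), pp)]), 0)
  i <- which.max(vals)
  list(value = vals[i], perm = perms[[i]])
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  # insert k at every position of every permutation of k-1 elements
  out <- vector("list", k * length(sub))
  idx <- 1
  for (s in sub) for (pos in 0:(k - 1)) {
    out[[idx]] <- append(s, k, after = pos)
    idx <- idx + 1
  }
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions
#' (Hubert-Arabie): from the contingency table `n_ij`,
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}] - E}}
#' with \eqn{E = \sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2} /
#' \binom{n}{2}}.  Equals 1 for identical partitions and is near 0 for
#' random ones.
#'
#' @param truth,pred equal-length label vectors.
#' @return A number \eqn{\le 1}.
#' @export
adjusted_rand_index <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(truth), length(pred)))
  n <- length(truth)
  tab <- table(truth, pred)
  a <- rowSums(tab); b <- colSums(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(a, 2)); sb <- sum(choose(b, 2))
  expected <- sa * sb / choose(n, 2)
  mx <- (sa + sb) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sij - expected) / (mx - expected)
}

#' Match fitted components to true groups
#'
#' Returns the accuracy-maximizing one-to-one assignment between predicted
#' components and true groups: an integer vector `m` with `m[g]` the index
#' of the fitted component corresponding to true group `g`.  Used to align
#' component indices before the estimation-error norms.
#'
#' @param truth true labels coded `1..G`.
#' @param pred predicted labels coded `1..G`.
#' @param G number of groups (default: largest code seen).
#' @return An integer permutation of `1..G`.
#' @export
match_components <- function(truth, pred, G = max(c(truth, pred))) {
  if (length(truth) != length(pred))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(truth), length(pred)))
  ct <- matrix(0, G, G)
  tab <- table(factor(truth, levels = 1:G), factor(pred, levels = 1:G))
  ct[, ] <- tab
  perm <- best_assignment(ct)$perm
  as.integer(perm)
}

#' Estimation-error norms
#'
#' Mean spectral-norm (`spectral_loss`) or Frobenius-norm
#' (`frobenius_loss`) distance between estimated and true parameter
#' matrices, averaged over components:
#' \eqn{\frac1G \sum_j \|\hat A_{m(j)} - A_j\|}.  For precision matrices
#' the estimate of component `j` is the Kronecker-assembled
#' \eqn{\hat V_j^{-1} \otimes \hat U_j^{-1}} (see
#' [assemble_precision()]); the same functions apply directly to mean
#' matrices.
#'
#' @param estimated,truth lists of conformable matrices (one per
#'   component).
#' @param matching optional permutation from [match_components()]:
#'   `estimated[[matching[j]]]` is compared with `truth[[j]]`.  Default is
#'   the identity.
#' @return The averaged norm (scalar).
#' @export
spectral_loss <- function(estimated, truth, matching = NULL) {
  pairwise_loss(estimated, truth, matching, function(D) norm(D, "2"))
}

#' @rdname spectral_loss
#' @export
frobenius_loss <- function(estimated, truth, matching = NULL) {
  pairwise_loss(estimated, truth, matching, function(D) norm(D, "F"))
}

pairwise_loss <- function(estimated, truth, matching, normf) {
  G <- length(truth)
  if (length(estimated) != G)
    stop("estimated and truth must have the same number of components")
  if (is.null(matching)) matching <- seq_len(G)
  vals <- vapply(seq_len(G), function(j) {
    E <- estimated[[matching[j]]]; Tr <- truth[[j]]
    if (!all(dim(E) == dim(Tr)))
      stop(sprintf("component %d: dimension mismatch %s vs %s", j,
                   paste(dim(E), collapse = "x"), paste(dim(Tr), collapse = "x")))
    normf(E - Tr)
  }, 0)
  mean(vals)
}

#' Assemble the full precision matrix of one component
#'
#' The covariance of `vec(X)` is \eqn{V \otimes U}, so the implied full
#' precision is \eqn{V^{-1} \otimes U^{-1}}.
#'
#' @param component one element of `model$components` from a fitted
#'   `pmnmm_model`.
#' @return A `pq x pq` precision matrix.
#' @export
assemble_precision <- function(component) {
  kronecker(component$Vinv, component$Uinv)
}
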