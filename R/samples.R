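#' Matrix sample sets
#'
#' A `matrix_samples` object is the container for a stack of `n` real
#' matrices of common size `p x q`, stored as a `p x q x n` array.  All
#' fitting, simulation and evaluation functions in the package accept
#' either such an object, a plain 3-D array with the same layout, or a
#' list of equally sized matrices.
#'
#' @param x a `p x q x n` numeric array or a list of `p x q` numeric
#'   matrices.
#' @return An object of class `matrix_samples`: the underlying array with
#'   dimensions `p`, `q`, `n`.
#' @examples
#' xs <- as_matrix_samples(list(diag(2), matrix(1, 2, 2)))
#' dim(xs)
#' @export
as_matrix_samples <- function(x) {
  if (inherits(x, "matrix_samples")) return(x)
  if (is.list(x)) {
    if (length(x) == 0L) stop("empty sample list: need n >= 1")
    dims <- lapply(x, dim)
    d1 <- dims[[1]]
    if (is.null(d1) || length(d1) != 2L)
      stop("sample list elements must be matrices")
    ok <- vapply(dims, function(d) identical(as.integer(d), as.integer(d1)),
                 logical(1))
    if (!all(ok))
      stop(sprintf("sample %d has dimensions %s, expected %dx%d",
                   which(!ok)[1],
                   paste(dims[[which(!ok)[1]]], collapse = "x"), d1[1], d1[2]))
    x <- array(unlist(x, use.names = FALSE), dim = c(d1[1], d1[2], length(x)))
  }
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("samples must be a p x q x n array or a list of p x q matrices")
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("samples contain missing values")
  structure(x, class = "matrix_samples")
}

#' @export
print.matrix_samples <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("matrix_samples: n = %d matrices of size %d x %d\n",
              d[3], d[1], d[2]))
  invisible(x)
}

# Number of samples / dimensions, used throughout.
sample_dims <- function(samples) {
  d <- dim(samples)
  list(p = d[1], q = d[2], n = d[3])
}

# Subset a sample set by index, keeping the class.
subset_samples <- function(samples, idx) {
  as_matrix_samples(samples[, , idx, drop = FALSE])
}

# n x pq matrix of column-stacked (vec) samples.
vectorize_samples <- function(samples) {
  d <- sample_dims(samples)
  t(matrix(samples, nrow = d$p * d$q, ncol = d$n))
}
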