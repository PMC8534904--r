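#' Read a matrix dataset from a directory of CSV files
#'
#' Each file `*.csv` in `path` (except `labels.csv`) holds one plain
#' numeric `p x q` grid without a header; files are read in lexicographic
#' order.  An optional `labels.csv` with one integer per line supplies
#' ground-truth labels in the same order.
#'
#' @param path directory containing the CSV files.
#' @return A list with `samples` (a [as_matrix_samples()] stack) and
#'   `labels` (integer vector or `NULL`).
#' @export
load_dataset <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path))
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  lab_file <- files[basename(files) == "labels.csv"]
  files <- files[basename(files) != "labels.csv"]
  if (!length(files)) stop(sprintf("no matrix CSV files found in %s", path))
  mats <- lapply(files, function(f) {
    m <- tryCatch(as.matrix(utils::read.table(f, sep = ",", header = FALSE)),
                  error = function(e) stop(sprintf("cannot parse %s: %s", f,
                                                   conditionMessage(e))))
    if (!is.numeric(m)) stop(sprintf("non-numeric content in %s", f))
    unname(m)
  })
  d1 <- dim(mats[[1]])
  for (i in seq_along(mats))
    if (!all(dim(mats[[i]]) == d1))
      stop(sprintf("%s is %dx%d but %s is %dx%d", basename(files[i]),
                   dim(mats[[i]])[1], dim(mats[[i]])[2], basename(files[1]),
                   d1[1], d1[2]))
  labels <- NULL
  if (length(lab_file)) {
    labels <- as.integer(utils::read.table(lab_file, header = FALSE)[[1]])
    if (length(labels) != length(mats))
      stop(sprintf("labels.csv has %d entries but there are %d matrices",
                   length(labels), length(mats)))
  }
  list(samples = as_matrix_samples(mats), labels = labels)
}

#' Write a matrix dataset as a directory of CSV files
#'
#' Inverse of [load_dataset()]: one zero-padded `sample_<i>.csv` per
#' matrix plus an optional `labels.csv`.
#'
#' @param samples a sample stack.
#' @param path output directory (created if missing).
#' @param labels optional integer labels.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(samples, path, labels = NULL) {
  samples <- as_matrix_samples(samples)
  d <- sample_dims(samples)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wd <- nchar(as.character(d$n))
  for (i in seq_len(d$n)) {
    f <- file.path(path, sprintf(paste0("sample_%0", wd, "d.csv"), i))
    utils::write.table(samples[, , i], f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(labels))
    utils::write.table(as.integer(labels), file.path(path, "labels.csv"),
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- "pmnmm-model/1"

#' Save or load a fitted mixture model as JSON
#'
#' All parameters (weights, per-component `M`, `U`, `V` and their
#' inverses, penalties, trace summary) are serialized at full double
#' precision together with a format-version field that is checked on load.
#'
#' @param model a `pmnmm_model`.
#' @param path file path of the JSON document.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed `pmnmm_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pmnmm_model"))
  doc <- list(
    format = MODEL_FORMAT_VERSION,
    G = model$G,
    weights = model$weights,
    penalties = unclass(model$penalties),
    components = lapply(model$components, function(cmp)
      lapply(cmp[c("M", "U", "V")], unclass)),
    trace = model$trace)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                                   conditionMessage(e))))
  if (is.null(doc$format))
    stop("unsupported model file: missing format version field")
  if (!identical(doc$format, MODEL_FORMAT_VERSION))
    stop(sprintf("unsupported model format '%s' (expected '%s')",
                 doc$format, MODEL_FORMAT_VERSION))
  components <- lapply(seq_len(doc$G), function(j) {
    cmp <- doc$components[[j]]
    new_component(as.matrix(cmp$M), as.matrix(cmp$U), as.matrix(cmp$V))
  })
  pen <- doc$penalties
  model <- new_mixture_model(doc$weights, components,
                             penalty_config(pen$lambda1, pen$lambda2,
                                            pen$lambda3))
  model$trace <- doc$trace
  model
}
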