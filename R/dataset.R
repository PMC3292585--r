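#' Labelled expression dataset
#'
#' Container for an N x K feature matrix (rows = samples, columns = features
#' identified by m/z ratios or gene IDs) with binary class labels. Intensities
#' may be negative (baseline-corrected spectra); missing or non-finite values
#' are rejected outright since the decomposition has no missing-data
#' mechanism.
#'
#' @param values numeric matrix, N samples x K features.
#' @param labels numeric vector of length N with values in \{1, -1\}
#'   (1 = disease/case, -1 = control).
#' @param feature_ids character vector of K feature identifiers.
#' @param sample_ids character vector of N sample identifiers.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `labels`, `feature_ids`, `sample_ids`.
#' @export
expression_dataset <- function(values, labels,
                               feature_ids = colnames(values),
                               sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); k <- ncol(values)
  if (n < 2L) stop("expression_dataset: need at least 2 samples, got ", n)
  if (k < 2L) stop("expression_dataset: need at least 2 features, got ", k)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression_dataset: values contain NaN/NA/Inf; ",
         "missing values are not supported")
  labels <- as.numeric(labels)
  if (length(labels) != n)
    stop("expression_dataset: ", length(labels), " labels for ", n, " samples")
  if (!all(labels %in% c(1, -1)))
    stop("expression_dataset: labels must be in {1, -1}; got {",
         paste(sort(unique(labels)), collapse = ", "), "}")
  if (is.null(feature_ids)) feature_ids <- sprintf("f%05d", seq_len(k))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != k)
    stop("expression_dataset: feature_ids length mismatch")
  if (length(sample_ids) != n)
    stop("expression_dataset: sample_ids length mismatch")
  dimnames(values) <- NULL
  structure(list(values = values, labels = labels,
                 feature_ids = feature_ids, sample_ids = sample_ids),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Labelled expression dataset\n")
  cat(sprintf("  %d samples x %d features\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  disease (y = 1): %d, control (y = -1): %d\n",
              sum(x$labels == 1), sum(x$labels == -1)))
  cat(sprintf("  features: %s ...\n",
              paste(head(x$feature_ids, 4L), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

subset_dataset <- function(dataset, idx) {
  expression_dataset(dataset$values[idx, , drop = FALSE],
                     dataset$labels[idx],
                     feature_ids = dataset$feature_ids,
                     sample_ids = dataset$sample_ids[idx])
}
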