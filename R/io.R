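## Plain-text IO: delimited expression matrices, component sets, CV reports.
## Delimiter is auto-detected among tab and comma; decimal point only.

detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

normalize_labels <- function(raw) {
  vals <- unique(raw)
  if (length(vals) != 2L)
    stop("label error: expected exactly 2 distinct label values, got {",
         paste(vals, collapse = ", "), "}")
  lower <- tolower(trimws(as.character(raw)))
  map <- c("1" = 1, "-1" = -1, "0" = -1,
           "case" = 1, "disease" = 1, "cancer" = 1,
           "control" = -1, "normal" = -1, "healthy" = -1)
  if (!all(lower %in% names(map)))
    stop("label error: unrecognised label values {",
         paste(setdiff(unique(lower), names(map)), collapse = ", "),
         "}; accepted aliases: 1/-1, 1/0, case/control")
  out <- unname(map[lower])
  if (length(unique(out)) != 2L)
    stop("label error: labels {", paste(vals, collapse = ", "),
         "} map to a single class")
  out
}

parse_numeric_body <- function(rows, start_row, path) {
  n <- length(rows)
  k <- length(rows[[1L]])
  mat <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    if (length(rows[[i]]) != k)
      stop("format error: ragged rows in ", path, " (row ", i + start_row - 1L,
           " has ", length(rows[[i]]), " fields, expected ", k, ")")
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(is.na(v) & !(tolower(rows[[i]]) %in% c("na", "nan")))
    if (length(bad))
      stop("parse error: non-numeric value '", rows[[i]][bad[1L]],
           "' at row ", i + start_row - 1L, ", column ", bad[1L],
           " of ", path)
    mat[i, ] <- v
  }
  mat
}

#' Read a labelled expression matrix from a delimited text file
#'
#' Reads a TSV or CSV matrix with one header row of feature IDs. Labels are
#' taken either from a designated column of the matrix file or from a separate
#' two-column file (sample_id, label). Accepted label encodings: \{1, -1\},
#' \{1, 0\}, \{case, control\} (and the obvious synonyms).
#'
#' @param path path to the matrix file.
#' @param label_column name of the label column inside the file (default
#'   `"label"`); ignored when `label_file` is given.
#' @param label_file optional path to a two-column file `sample_id<TAB>label`.
#' @param orientation `"rows"` if rows are samples (default), `"columns"` if
#'   the file stores features as rows; the returned dataset always has rows =
#'   samples.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, label_column = "label",
                                   label_file = NULL,
                                   orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("format error: ", path, " has no data rows")
  delim <- detect_delim(lines[[1L]])
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(fields[[1L]])
  body <- lapply(fields[-1L], trimws)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1L]
    stop("format error: ragged rows in ", path, " (row ", bad + 1L,
         " has ", widths[bad], " fields, header has ", length(header), ")")
  }

  has_rownames <- header[1L] == "" || tolower(header[1L]) %in% c("id", "sample", "sample_id", "feature", "feature_id")
  row_ids <- NULL
  if (has_rownames) {
    header <- header[-1L]
    row_ids <- vapply(body, `[`, character(1L), 1L)
    body <- lapply(body, `[`, -1L)
  }

  labels_raw <- NULL
  if (is.null(label_file)) {
    li <- which(header == label_column)
    if (length(li) != 1L)
      stop("label error: label column '", label_column, "' not found in ", path)
    labels_raw <- vapply(body, `[`, character(1L), li)
    header <- header[-li]
    body <- lapply(body, `[`, -li)
  }

  mat <- parse_numeric_body(body, 2L, path)

  if (orientation == "columns") {
    mat <- t(mat)
    tmp <- row_ids
    row_ids <- header
    header <- tmp
    if (is.null(header)) header <- sprintf("f%05d", seq_len(ncol(mat)))
  }

  if (!is.null(label_file)) {
    lab_lines <- readLines(label_file)
    lab_lines <- lab_lines[nzchar(lab_lines)]
    lab_fields <- strsplit(lab_lines, detect_delim(lab_lines[[1L]]), fixed = TRUE)
    lab_ids <- vapply(lab_fields, `[`, character(1L), 1L)
    lab_vals <- vapply(lab_fields, `[`, character(1L), 2L)
    if (!is.null(row_ids)) {
      m <- match(row_ids, lab_ids)
      if (anyNA(m))
        stop("label error: no label for sample(s) ",
             paste(row_ids[is.na(m)], collapse = ", "))
      labels_raw <- lab_vals[m]
    } else {
      if (length(lab_vals) != nrow(mat))
        stop("label error: ", length(lab_vals), " labels for ",
             nrow(mat), " samples")
      labels_raw <- lab_vals
    }
  }

  expression_dataset(mat, normalize_labels(labels_raw),
                     feature_ids = header, sample_ids = row_ids)
}

#' Write a labelled expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: one header row of feature IDs plus a
#' `label` column, rows = samples, full precision.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", dataset$feature_ids, "label"),
                   collapse = "\t"), con)
  body <- apply(dataset$values, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = "\t"))
  writeLines(paste(dataset$sample_ids, body, dataset$labels, sep = "\t"), con)
  invisible(path)
}

#' Write the four labelled component sets to a directory
#'
#' One TSV per set (named by its reference/role pair, e.g.
#' `controlref_disease.tsv`) plus a JSON manifest recording dimensions and the
#' extraction parameters (M, delta_theta, lambda multiplier).
#'
#' @param sets a `component_sets` object as returned by [extract_feature_sets()]
#'   or found in a [refsca()] fit.
#' @param out_dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_component_sets <- function(sets, out_dir) {
  stopifnot(inherits(sets, "component_sets"))
  if (!length(sets$sets) || any(vapply(sets$sets, nrow, 1L) == 0L))
    stop("no components extracted")
  dims <- vapply(sets$sets, dim, integer(2L))
  if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L)
    stop("dimension error: component sets have inconsistent shapes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(sets$sets)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    ds <- expression_dataset(sets$sets[[nm]], sets$labels,
                             feature_ids = sets$feature_ids,
                             sample_ids = sets$sample_ids)
    write_expression_matrix(ds, f)
    files <- c(files, f)
  }
  manifest <- list(sets = names(sets$sets),
                   n_samples = unname(dims[1L, 1L]),
                   n_features = unname(dims[2L, 1L]),
                   params = sets$params)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Read component sets written by [write_component_sets()]
#'
#' @param dir directory containing the set TSVs and `manifest.json`.
#' @return A `component_sets` object.
#' @export
read_component_sets <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sets <- list()
  labels <- NULL; fids <- NULL; sids <- NULL
  for (nm in manifest$sets) {
    ds <- read_expression_matrix(file.path(dir, paste0(nm, ".tsv")))
    sets[[nm]] <- ds$values
    labels <- ds$labels; fids <- ds$feature_ids; sids <- ds$sample_ids
  }
  structure(list(sets = sets, labels = labels, feature_ids = fids,
                 sample_ids = sids, params = manifest$params),
            class = "component_sets")
}

#' Write a cross-validation report as JSON
#'
#' @param report a `cv_report` from [repeated_two_fold_cv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  out <- unclass(report)
  out$per_evaluation <- as.list(as.data.frame(out$per_evaluation))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cross-validation report written by [write_cv_report()]
#'
#' @param path path to the JSON report.
#' @return A `cv_report` object.
#' @export
read_cv_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$per_evaluation <- as.data.frame(raw$per_evaluation)
  structure(raw, class = "cv_report")
}
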