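#' Construct an expression matrix
#'
#' A thin validating wrapper around a numeric features-by-samples matrix.
#' Row names are feature (isomiR) identifiers, column names are sample
#' identifiers; a `unit` attribute records whether entries are raw read
#' counts or RPM (reads per million mapped reads).
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique row and column names and no negative or missing entries.
#' @param unit `"counts"` or `"rpm"`.
#' @return The validated matrix with class `expr_matrix` and attribute
#'   `unit`.
#' @export
expr_matrix <- function(values, unit = c("counts", "rpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_data("expression matrix must have at least one feature and one sample")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_data("expression matrix needs feature row names and sample column names")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop_data("duplicated feature ids: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop_data("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  if (anyNA(values)) stop_data("expression matrix contains missing values")
  if (any(values < 0)) stop_data("expression matrix contains negative values")
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x), " features x ", ncol(x), " samples (",
      attr(x, "unit"), ")\n", sep = "")
  invisible(x)
}

expr_unit <- function(x) attr(x, "unit") %||% "counts"

#' Convert raw counts to reads per million (RPM)
#'
#' Each count is divided by the sample's library size and scaled by 1e6.
#' When library sizes equal the column sums (the default), every RPM column
#' sums to one million.
#'
#' @param counts An [expr_matrix()] of raw counts.
#' @param library_sizes Optional vector of per-sample library sizes
#'   (strictly positive), one per column; defaults to the column sums.
#' @return An `expr_matrix` with unit `"rpm"`.
#' @export
compute_rpm <- function(counts, library_sizes = NULL) {
  if (!inherits(counts, "expr_matrix")) counts <- expr_matrix(counts)
  if (identical(expr_unit(counts), "rpm"))
    stop_data("matrix is already in RPM")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (length(library_sizes) != ncol(counts))
    stop_data("need one library size per sample (",
              ncol(counts), "), got ", length(library_sizes))
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop_data("library sizes must all be strictly positive")
  rpm <- sweep(unclass(counts), 2L, library_sizes, `/`) * 1e6
  expr_matrix(rpm, unit = "rpm")
}

#' Read an expression matrix from TSV
#'
#' Expects a header line `isomir_id<TAB>sample1<TAB>...` and one feature per
#' row; all cells numeric, UTF-8.
#'
#' @param path Path to the TSV file.
#' @param unit Unit to record on the returned matrix (`"counts"` or
#'   `"rpm"`); the file format does not carry it.
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path, unit = c("counts", "rpm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop_data("expression matrix file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          encoding = "UTF-8", data.table = TRUE)
  if (ncol(dt) < 2L)
    stop_data("expression TSV needs an id column plus at least one sample: ",
              path)
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop_data("non-numeric expression cells in ", path)
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  expr_matrix(vals, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Values are written at full precision so that a read/write round trip
#' preserves them beyond 12 significant digits.
#'
#' @param matrix An [expr_matrix()] (or plain named numeric matrix).
#' @param path Output path; written atomically.
#' @return The path, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  if (!inherits(matrix, "expr_matrix")) matrix <- expr_matrix(matrix)
  dt <- data.table::data.table(isomir_id = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(unclass(matrix)))
  write_atomic(function(tmp)
    data.table::fwrite(dt, tmp, sep = "\t", quote = FALSE), path)
  invisible(path)
}

#' Read sample subtype labels from TSV
#'
#' Expects a header `sample_id<TAB>subtype` and one sample per row.
#'
#' @param path Path to the TSV file.
#' @return A named factor of subtype labels (names are sample ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_data("labels file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          encoding = "UTF-8")
  if (ncol(dt) < 2L)
    stop_data("labels TSV needs columns sample_id and subtype: ", path)
  ids <- as.character(dt[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_data("duplicated sample ids in labels: ", paste(dup, collapse = ", "))
  labels <- factor(as.character(dt[[2L]]))
  names(labels) <- ids
  labels
}

#' Write sample labels to TSV
#'
#' @param labels Named factor or character vector of subtype labels.
#' @param path Output path; written atomically.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (is.null(names(labels))) stop_data("labels must be named by sample id")
  dt <- data.table::data.table(sample_id = names(labels),
                               subtype = as.character(labels))
  write_atomic(function(tmp)
    data.table::fwrite(dt, tmp, sep = "\t", quote = FALSE), path)
  invisible(path)
}

#' Align a label vector to the columns of an expression matrix
#'
#' Errors if any matrix sample lacks a label, naming the offenders; extra
#' labelled samples absent from the matrix are dropped.
#'
#' @param matrix An [expr_matrix()].
#' @param labels Named factor from [read_labels()].
#' @return A factor ordered like `colnames(matrix)` with unused levels
#'   dropped.
#' @export
align_labels <- function(matrix, labels) {
  if (is.null(names(labels))) stop_data("labels must be named by sample id")
  missing <- setdiff(colnames(matrix), names(labels))
  if (length(missing))
    stop_data("samples missing from labels: ", paste(missing, collapse = ", "))
  out <- droplevels(labels[colnames(matrix)])
  names(out) <- colnames(matrix)
  out
}

# 0/1 label distance matrix: d(y_i, y_j) = 0 iff the labels are equal
label_distance_matrix <- function(labels) {
  y <- as.integer(factor(labels))
  d <- outer(y, y, `!=`) * 1
  d
}
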