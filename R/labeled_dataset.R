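#' Two-class labeled dataset
#'
#' Container for a numeric sample-by-variable matrix with one binary class
#' label per row.  All effect-size and evaluation functions in the package
#' operate on this class.  Classes are ordered by `sort()` of their unique
#' labels; the sign of every per-variable Cohen's d is (first class minus
#' second class) under that ordering.
#'
#' @param values numeric matrix or data frame, rows = samples, columns =
#'   variables.  No missing values are allowed: clean or reject upstream.
#' @param labels vector of class labels, one per row; exactly two distinct
#'   values must be present for effect sizes to be computed.
#' @param variable_names optional character vector of column names; defaults
#'   to the column names of `values` or `V1..Vp`.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `values` (numeric matrix), `labels` (factor with two levels in sorted
#'   order) and `variable_names`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(40), 20, 2), rep(c("a", "b"), each = 10))
#' print(d)
#' @export
labeled_dataset <- function(values, labels, variable_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_mlsize("input_error", "`values` must be a numeric matrix or data frame")
  }
  if (anyNA(values) || anyNA(labels)) {
    stop_mlsize("input_error", "missing values are not allowed; remove or impute them first")
  }
  if (length(labels) != nrow(values)) {
    stop_mlsize("input_error", sprintf(
      "length of `labels` (%d) does not match number of rows (%d)",
      length(labels), nrow(values)))
  }
  lv <- sort(unique(as.character(labels)))
  labels <- factor(as.character(labels), levels = lv)
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
    if (is.null(variable_names)) variable_names <- paste0("V", seq_len(ncol(values)))
  }
  colnames(values) <- variable_names
  structure(
    list(values = values, labels = labels, variable_names = variable_names),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("  classes:", paste(sprintf("%s (n=%d)", levels(x$labels),
                                  tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$values)

# Validate the two-class contract before any effect-size computation.
# Returns the per-class row indices in sorted label order.
check_two_class <- function(dataset, min_per_class = 2L) {
  if (!inherits(dataset, "labeled_dataset")) {
    stop_mlsize("input_error", "expected a `labeled_dataset`")
  }
  lv <- levels(dataset$labels)
  present <- lv[tabulate(dataset$labels, length(lv)) > 0]
  if (length(present) != 2L) {
    stop_mlsize("two_class_error", sprintf(
      "exactly two classes are required, found %d", length(present)))
  }
  idx <- split(seq_along(dataset$labels), dataset$labels)
  if (any(lengths(idx) < min_per_class)) {
    stop_mlsize("two_class_error", sprintf(
      "each class needs at least %d samples (found %s)", min_per_class,
      paste(lengths(idx), collapse = ", ")))
  }
  idx
}

#' Read a two-class dataset from CSV
#'
#' Reads a comma-separated file with a header row, numeric feature columns
#' and one designated label column.
#'
#' @param path path to the CSV file (UTF-8, `.` decimal separator).
#' @param label_column name of the label column (default `"label"`).
#' @return A [labeled_dataset()].
#' @export
read_labeled_csv <- function(path, label_column = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop_mlsize("input_error", sprintf(
      "label column '%s' not found in %s", label_column, path))
  }
  labels <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad)) {
    stop_mlsize("input_error", sprintf(
      "non-numeric feature column(s): %s", paste(bad, collapse = ", ")))
  }
  labeled_dataset(as.matrix(feats), labels, variable_names = names(feats))
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [read_labeled_csv()]: features plus one label column.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @param label_column name for the label column.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(dataset, path, label_column = "label") {
  df <- as.data.frame(dataset$values)
  df[[label_column]] <- as.character(dataset$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
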