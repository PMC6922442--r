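#' Validate an ensemble of model outputs
#'
#' An ensemble is a plain data frame with one row per model (observation) and
#' one numeric column per variable, e.g. the flux control coefficients of a
#' target flux across a population of sampled kinetic models. Every
#' data-frame-first function in emci runs its input through this check.
#'
#' @param data A data frame: n rows (models), p numeric columns (variables).
#' @param min_rows Minimum number of rows required (2 by default, so that a
#'   sample standard deviation exists).
#' @return The validated numeric matrix (invisibly usable downstream), with
#'   column names taken from `data`.
#' @keywords internal
validate_ensemble <- function(data, min_rows = 2) {
  if (!is.data.frame(data) && !is.matrix(data)) {
    abort("`data` must be a data frame or matrix of model outputs.",
          class = "emci_validation_error")
  }
  x <- as.matrix(data)
  if (!is.numeric(x)) {
    bad <- if (is.data.frame(data)) {
      names(data)[!vapply(data, is.numeric, logical(1))]
    } else "matrix"
    abort(paste0("All ensemble columns must be numeric; offending: ",
                 paste(bad, collapse = ", ")),
          class = "emci_validation_error")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  if (anyDuplicated(colnames(x))) {
    abort("Variable names must be unique.", class = "emci_validation_error")
  }
  if (ncol(x) < 1) {
    abort("Ensemble must have at least one variable.",
          class = "emci_validation_error")
  }
  if (nrow(x) < min_rows) {
    abort(sprintf("Ensemble must have at least %d rows (models); got %d.",
                  min_rows, nrow(x)),
          class = "emci_validation_error")
  }
  if (!all(is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-finite value at row %d, column '%s'; missing values are rejected, not imputed.",
      idx[1], colnames(x)[idx[2]]),
      class = "emci_validation_error")
  }
  x
}

#' Read an ensemble matrix from delimited text
#'
#' Reads a header-plus-numeric-body TSV (or CSV) file into an ensemble tibble:
#' the header row names the variables, each subsequent row is one model.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter, `"\t"` (default) or `","`.
#' @param case_label Optional free-text label attached as the `"case_label"`
#'   attribute (used when comparing cases).
#' @return A tibble with n rows and p numeric columns.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_ensemble(data.frame(A = c(1, 2, 3), B = c(4, 5, 6)), tf)
#' read_ensemble(tf)
#' @export
read_ensemble <- function(path, delimiter = "\t", case_label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "emci_io_error")
  }
  # readr's own parse warning is redundant: problems() is inspected below and
  # re-raised as a typed error naming the offending cell
  out <- suppressWarnings(readr::read_delim(
    path, delim = delimiter, col_types = readr::cols(.default = readr::col_double()),
    name_repair = "minimal", progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Non-numeric cell at data row %d, column %d of %s (expected %s, got '%s').",
      probs$row[1], probs$col[1], path, probs$expected[1], probs$actual[1]),
      class = "emci_parse_error")
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("Duplicate variable names in header of %s: %s", path,
                  paste(unique(names(out)[duplicated(names(out))]), collapse = ", ")),
          class = "emci_validation_error")
  }
  validate_ensemble(out)
  if (!is.null(case_label)) attr(out, "case_label") <- case_label
  out
}

#' Write an ensemble matrix to delimited text
#'
#' @param data Ensemble data frame (see [validate_ensemble()]).
#' @param path Output path.
#' @param delimiter Field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(data, path, delimiter = "\t") {
  validate_ensemble(data, min_rows = 1)
  readr::write_delim(as_tibble(as.data.frame(data)), path, delim = delimiter,
                     progress = FALSE)
  invisible(path)
}

#' Write a confidence-interval table to TSV
#'
#' Serializes a [ci_set][univariate_ci] to a tab-separated table with columns
#' `variable`, `mean`, `lower`, `upper`, `significant`, `method`,
#' `simultaneous_level` — the tabular form of what interval plots display.
#' Values survive a read round-trip at full double precision.
#'
#' @param ciset A `ci_set` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ci_table <- function(ciset, path) {
  stopifnot(inherits(ciset, "ci_set"))
  tab <- tidy(ciset)[, c("variable", "mean", "lower", "upper", "significant")]
  tab$method <- ciset$method
  tab$simultaneous_level <- ciset$simultaneous_level
  if (nrow(tab) == 0) {
    warn("Writing a header-only CI table: the CI set has no variables.")
  }
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read back a confidence-interval table
#'
#' @param path Path to a table written by [write_ci_table()].
#' @return A tibble with the table's columns.
#' @export
read_ci_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
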