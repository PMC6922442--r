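#' Drop variables with negligible variation
#'
#' Data-preparation step run before any interval construction: variables whose
#' sample standard deviation falls below a tolerance carry no usable
#' uncertainty signal (typically numerically frozen model outputs) and are
#' removed. Sample SDs use the n-1 denominator.
#'
#' @param data Ensemble data frame.
#' @param tol Nonnegative SD tolerance; default `1e-9`.
#' @return The ensemble restricted to columns with SD >= `tol`, original
#'   column order preserved. Removed variable names are attached as the
#'   `"removed_variables"` attribute and reported via a message.
#' @examples
#' d <- data.frame(a = rnorm(10), frozen = rep(1, 10))
#' filter_low_variance(d)
#' @export
filter_low_variance <- function(data, tol = 1e-9) {
  stopifnot(is.numeric(tol), length(tol) == 1, tol >= 0)
  x <- validate_ensemble(data)
  sds <- apply(x, 2, sd)
  keep <- sds >= tol
  if (!any(keep)) {
    abort("All variables fall below the SD tolerance; nothing to analyze.",
          class = "emci_validation_error")
  }
  removed <- colnames(x)[!keep]
  out <- as_tibble(as.data.frame(x[, keep, drop = FALSE]))
  attr(out, "removed_variables") <- removed
  attr(out, "case_label") <- attr(data, "case_label", exact = TRUE)
  if (length(removed) > 0) {
    inform(sprintf("Removed %d variable(s) with SD < %g: %s",
                   length(removed), tol, paste(removed, collapse = ", ")))
  }
  out
}

#' Rank variables by absolute mean
#'
#' @param data Ensemble data frame.
#' @return Character vector of variable names sorted by decreasing absolute
#'   sample mean; ties keep the original column order (stable sort).
#' @export
rank_by_abs_mean <- function(data) {
  x <- validate_ensemble(data, min_rows = 1)
  m <- abs(colMeans(x))
  colnames(x)[order(-m)]  # order() is stable, so ties keep input order
}
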