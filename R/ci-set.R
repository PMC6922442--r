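# Fitted-object container shared by all four interval constructions.
new_ci_set <- function(estimates, method, alpha_s, alpha, n,
                       simultaneous_level, seed = NULL, B = NULL, M = NULL,
                       critical_value = NULL) {
  estimates[] <- lapply(estimates, unname)
  estimates$significant <- estimates$lower > 0 | estimates$upper < 0
  structure(
    list(
      estimates = estimates,
      method = method,
      alpha_s = alpha_s,
      alpha = alpha,
      per_variable_level = 1 - alpha,
      simultaneous_level = simultaneous_level,
      n = n,
      seed = seed, B = B, M = M,
      critical_value = critical_value
    ),
    class = "ci_set"
  )
}

#' @export
print.ci_set <- function(x, ...) {
  cat(sprintf(
    "<ci_set> %s intervals for %d variables (n = %d models)\n",
    x$method, nrow(x$estimates), x$n))
  cat(sprintf("  simultaneous level: %.4g; per-variable level: %.4g\n",
              x$simultaneous_level, x$per_variable_level))
  cat(sprintf("  significant (CI excludes 0): %d / %d\n",
              sum(x$estimates$significant), nrow(x$estimates)))
  print(x$estimates, n = 6)
  invisible(x)
}

#' Tidy a set of confidence intervals
#'
#' @param x A `ci_set`.
#' @param ... Unused.
#' @return A tibble with one row per variable: `variable`, `mean`, `lower`,
#'   `upper`, `width`, `significant`, `method`.
#' @method tidy ci_set
#' @export
tidy.ci_set <- function(x, ...) {
  out <- x$estimates
  out$width <- out$upper - out$lower
  out$method <- x$method
  out[, c("variable", "mean", "lower", "upper", "width", "significant", "method")]
}

#' One-row summary of a set of confidence intervals
#'
#' @param x A `ci_set`.
#' @param ... Unused.
#' @method glance ci_set
#' @export
glance.ci_set <- function(x, ...) {
  tibble(
    method = x$method,
    n = x$n,
    p = nrow(x$estimates),
    alpha_s = x$alpha_s,
    simultaneous_level = x$simultaneous_level,
    per_variable_level = x$per_variable_level,
    n_significant = sum(x$estimates$significant),
    mean_width = mean(x$estimates$upper - x$estimates$lower)
  )
}

#' Interval plot for a set of confidence intervals
#'
#' Variables are ordered by decreasing absolute mean; intervals that exclude
#' zero are highlighted.
#'
#' @param object A `ci_set`.
#' @param top_n Plot at most this many variables (largest absolute means).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_set
#' @export
autoplot.ci_set <- function(object, top_n = Inf, ...) {
  d <- tidy(object)
  d <- d[order(-abs(d$mean)), ]
  if (is.finite(top_n)) d <- utils::head(d, top_n)
  d$variable <- factor(d$variable, levels = d$variable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable, y = .data$mean,
                                  colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             shape = 18) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      name = "excludes 0") +
    ggplot2::labs(x = NULL, y = "mean with simultaneous CI",
                  title = sprintf("%s intervals (simultaneous level %.3g)",
                                  object$method, object$simultaneous_level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Significance flags from a CI set
#'
#' A variable is flagged significant when its interval excludes zero — the
#' CI/test duality at the set's simultaneous level.
#'
#' @param ciset A `ci_set`.
#' @return A tibble with columns `variable` and `significant`.
#' @export
significance_flags <- function(ciset) {
  stopifnot(inherits(ciset, "ci_set"))
  ciset$estimates[, c("variable", "significant")]
}
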