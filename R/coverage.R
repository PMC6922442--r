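#' Coverage experiment for a confidence-interval method
#'
#' Operationalizes what coverage means: the proportion of repetitions of the
#' whole sampling experiment in which the intervals contain the true means.
#' Draws `reps` independent ensembles from a known-truth [copula_spec()],
#' builds intervals with the requested method on each, and records (a)
#' simultaneous coverage — the fraction of repetitions in which *all* true
#' means are inside their intervals — and (b) per-variable marginal
#' coverages with left/right miss rates (true mean below the lower or above
#' the upper limit).
#'
#' @param spec A [copula_spec()] (the estimand is `spec$true_means`).
#' @param method `"univariate"`, `"bonferroni"`, `"exact_normal"` or
#'   `"bootstrap"`. For the univariate method `alpha_s` is used as the
#'   per-variable level, exposing the uncorrected family-wise coverage.
#' @param alpha_s Error level; default 0.05.
#' @param n Models per simulated ensemble.
#' @param reps Repetitions; at least 100.
#' @param seed Integer seed driving the entire experiment.
#' @param B Bootstrap replicates per repetition (bootstrap method).
#' @param M Monte Carlo draws for the equicoordinate quantile (exact_normal).
#' @return A `coverage_report`: simultaneous coverage, per-variable tibble of
#'   marginal coverage / miss rates / mean widths, and the experiment settings.
#' @export
run_coverage_experiment <- function(spec, method = c("bonferroni", "univariate",
                                                     "exact_normal", "bootstrap"),
                                    alpha_s = 0.05, n = 500, reps = 500,
                                    seed = NULL, B = 1000, M = 20000) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "copula_spec"), reps >= 100, n >= 2)
  mu <- spec$true_means
  p <- spec$p
  with_seed_if(seed, {
    all_in <- logical(reps)
    inside <- matrix(0, reps, p)
    left <- matrix(0, reps, p)
    width <- matrix(0, reps, p)
    for (i in seq_len(reps)) {
      ens <- generate_copula_ensemble(spec, n)
      cs <- switch(method,
        univariate   = univariate_ci(ens, alpha = alpha_s),
        bonferroni   = bonferroni_ci(ens, alpha_s = alpha_s),
        exact_normal = exact_normal_ci(ens, alpha_s = alpha_s, M = M),
        bootstrap    = balanced_simultaneous_ci(ens, alpha_s = alpha_s, B = B))
      lo <- cs$estimates$lower; hi <- cs$estimates$upper
      inside[i, ] <- mu >= lo & mu <= hi
      left[i, ] <- mu < lo
      width[i, ] <- hi - lo
      all_in[i] <- all(inside[i, ] == 1)
    }
    structure(
      list(
        simultaneous_coverage = mean(all_in),
        per_variable = tibble(
          variable = spec$variable_names,
          coverage = colMeans(inside),
          miss_left = colMeans(left),
          miss_right = 1 - colMeans(inside) - colMeans(left),
          mean_width = colMeans(width)
        ),
        method = method, alpha_s = alpha_s, n = n, reps = reps,
        seed = seed, B = if (method == "bootstrap") B else NULL,
        M = if (method == "exact_normal") M else NULL
      ),
      class = "coverage_report"
    )
  })
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> %s at alpha_s = %g: simultaneous coverage %.3f (%d reps, n = %d)\n",
    x$method, x$alpha_s, x$simultaneous_coverage, x$reps, x$n))
  print(x$per_variable, n = 6)
  invisible(x)
}

#' Per-variable rates from a coverage report
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @return The per-variable tibble: `variable`, `coverage`, `miss_left`,
#'   `miss_right`, `mean_width`.
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) x$per_variable

#' One-row summary of a coverage report
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble(
    method = x$method, alpha_s = x$alpha_s, n = x$n, reps = x$reps,
    simultaneous_coverage = x$simultaneous_coverage,
    mc_se = sqrt(x$alpha_s * (1 - x$alpha_s) / x$reps),
    min_marginal_coverage = min(x$per_variable$coverage),
    max_tail_imbalance = max(abs(x$per_variable$miss_left -
                                   x$per_variable$miss_right))
  )
}

#' Plot marginal coverages and tail miss rates
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_variable,
                           c("coverage", "miss_left", "miss_right"),
                           names_to = "rate", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable, y = .data$value,
                                  fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1 - object$alpha_s, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "rate",
                  title = sprintf("%s: simultaneous coverage %.3f (nominal %.3f)",
                                  object$method, object$simultaneous_coverage,
                                  1 - object$alpha_s)) +
    ggplot2::theme_minimal()
}
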