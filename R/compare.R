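#' Preselect the most important significant variables per case
#'
#' Case-study preselection: for each case, keep the `k` variables with the
#' largest absolute mean among those whose interval excludes zero (fewer if
#' fewer are significant), then take the union across cases. Keeps the number
#' of downstream pairwise comparisons manageable while retaining every
#' variable that matters in at least one case.
#'
#' @param cisets A list of `ci_set` objects, one per case (typically from
#'   [balanced_simultaneous_ci()]).
#' @param k Variables kept per case; default 7.
#' @return Character vector: the union of per-case selections, sorted.
#' @export
preselect_top_variables <- function(cisets, k = 7) {
  stopifnot(k >= 1, length(cisets) >= 1,
            all(vapply(cisets, inherits, logical(1), "ci_set")))
  picks <- lapply(cisets, function(cs) {
    est <- cs$estimates[cs$estimates$significant, , drop = FALSE]
    est <- est[order(-abs(est$mean)), , drop = FALSE]  # stable: ties keep order
    utils::head(est$variable, k)
  })
  sel <- sort(unique(unlist(picks)))
  if (length(sel) == 0) {
    warn("No variable is significant in any case; selection is empty.")
  }
  sel
}

#' Mean differences and standard errors for all case pairs
#'
#' For each unordered pair of cases (A, B) and each requested variable j,
#' computes `d = mean_A[j] - mean_B[j]` with standard error
#' `sqrt(s2_A[j]/n_A + s2_B[j]/n_B)`.
#'
#' @param ensembles Named list of ensemble data frames (the cases); unnamed
#'   lists are labelled Case1, Case2, ...
#' @param variables Variables to compare; default all variables common to
#'   every case by the first ensemble's column order.
#' @return A tibble with columns `case_a`, `case_b`, `variable`, `diff`, `se`.
#' @export
pairwise_differences <- function(ensembles, variables = NULL) {
  ens <- check_cases(ensembles, variables)
  pairs <- utils::combn(names(ens$x), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(
      case_a = a, case_b = b, variable = ens$variables,
      diff = unname(ens$means[[a]] - ens$means[[b]]),
      se = unname(sqrt(ens$vars[[a]] / ens$n[[a]] + ens$vars[[b]] / ens$n[[b]]))
    )
  })
  dplyr::bind_rows(rows)
}

# Validate a list of case ensembles against a common variable set and
# precompute per-case means/variances.
check_cases <- function(ensembles, variables = NULL) {
  stopifnot(is.list(ensembles), length(ensembles) >= 2)
  if (is.null(names(ensembles)) || any(names(ensembles) == "")) {
    names(ensembles) <- paste0("Case", seq_along(ensembles))
  }
  x <- lapply(ensembles, validate_ensemble)
  if (is.null(variables)) {
    variables <- Reduce(intersect, lapply(x, colnames))
    variables <- colnames(x[[1]])[colnames(x[[1]]) %in% variables]
  }
  if (length(variables) == 0) {
    abort("No variables to compare.", class = "emci_validation_error")
  }
  for (nm in names(x)) {
    missing <- setdiff(variables, colnames(x[[nm]]))
    if (length(missing) > 0) {
      abort(sprintf("Case '%s' lacks variable(s): %s", nm,
                    paste(missing, collapse = ", ")),
            class = "emci_validation_error")
    }
    x[[nm]] <- x[[nm]][, variables, drop = FALSE]
  }
  list(
    x = x, variables = variables,
    n = lapply(x, nrow),
    means = lapply(x, colMeans),
    vars = lapply(x, function(m) apply(m, 2, var))
  )
}

#' Globally corrected mean-difference intervals across cases
#'
#' Compares every unordered pair of cases on every requested variable through
#' confidence intervals for the difference of means, with the simultaneity
#' correction applied globally over all `q_total = pairs x variables`
#' comparisons at once, never per pair. A difference is significant when its
#' interval excludes zero.
#'
#' Methods:
#' \describe{
#'   \item{univariate}{z interval at `alpha_s` per comparison, no correction —
#'     the misleading baseline.}
#'   \item{bonferroni}{z interval at `alpha_s / q_total` per comparison.}
#'   \item{exact_normal}{equicoordinate quantile of the `q_total`-dimensional
#'     normal whose covariance is assembled from the per-case sample
#'     covariances. Comparisons sharing a case are correlated:
#'     `Cov(d_AB, d_AC) = Sigma_A / n_A` (sign-flipped when the shared case
#'     sits on opposite sides of the two differences).}
#'   \item{bootstrap}{every case is resampled independently within each
#'     replicate, all `q_total` differences are recomputed, and the balanced
#'     max-rank construction is applied in the difference space.}
#' }
#'
#' @inheritParams pairwise_differences
#' @param method One of `"univariate"`, `"bonferroni"`, `"exact_normal"`,
#'   `"bootstrap"`.
#' @param alpha_s Simultaneous error level over all comparisons; default 0.05.
#' @param B Bootstrap replicates (bootstrap method).
#' @param M Monte Carlo draws for the equicoordinate quantile (exact_normal).
#' @param seed Optional integer seed (stochastic methods).
#' @param shared_case_blocks For `exact_normal`: include the cross-pair
#'   covariance induced by a shared case (default) or zero those blocks and
#'   treat distinct comparisons as uncorrelated across pairs.
#' @return A `comparison_set`: tidy()-able object whose `comparisons` tibble
#'   has one row per (case pair, variable).
#' @export
compare_cases <- function(ensembles, variables = NULL,
                          method = c("bootstrap", "bonferroni", "exact_normal",
                                     "univariate"),
                          alpha_s = 0.05, B = 2000, M = 1e5, seed = NULL,
                          shared_case_blocks = TRUE) {
  method <- match.arg(method)
  stopifnot(alpha_s > 0, alpha_s < 1)
  ens <- check_cases(ensembles, variables)
  d <- pairwise_differences(ens$x, ens$variables)
  q_total <- nrow(d)
  if (q_total == 0) abort("No comparisons to make.", class = "emci_validation_error")

  crit <- NA_real_
  if (method == "univariate") {
    crit <- qnorm(1 - alpha_s / 2)
    d$lower <- d$diff - crit * d$se
    d$upper <- d$diff + crit * d$se
  } else if (method == "bonferroni") {
    crit <- qnorm(1 - alpha_s / (2 * q_total))
    if (!is.finite(crit)) {
      abort("alpha_s / q_total underflowed; too many comparisons.",
            class = "emci_validation_error")
    }
    d$lower <- d$diff - crit * d$se
    d$upper <- d$diff + crit * d$se
  } else if (method == "exact_normal") {
    corr <- difference_correlation(ens, shared_case_blocks)
    crit <- exact_normal_quantile(corr, alpha_s = alpha_s, M = M, seed = seed)
    d$lower <- d$diff - crit * d$se
    d$upper <- d$diff + crit * d$se
  } else {
    boot <- bootstrap_differences(ens, B = B, seed = seed)
    bal <- balanced_max_rank(boot, alpha_s)
    d$lower <- bal$lower
    d$upper <- bal$upper
  }
  d$significant <- d$lower > 0 | d$upper < 0

  structure(
    list(comparisons = d, method = method, alpha_s = alpha_s,
         simultaneous_level = if (method == "univariate") NA_real_ else 1 - alpha_s,
         q_total = q_total, n_pairs = choose(length(ens$x), 2),
         variables = ens$variables, cases = names(ens$x),
         critical_value = crit, B = if (method == "bootstrap") B else NULL,
         M = if (method == "exact_normal") M else NULL, seed = seed),
    class = "comparison_set"
  )
}

# q_total x q_total correlation of the difference vector, from per-case
# sample covariances. Rows are ordered as pairwise_differences() orders them:
# pair-major, variable-minor.
difference_correlation <- function(ens, shared_case_blocks = TRUE) {
  k <- length(ens$variables)
  covs <- lapply(ens$x, function(m) cov(m[, ens$variables, drop = FALSE]))
  pairs <- utils::combn(names(ens$x), 2)
  np <- ncol(pairs)
  V <- matrix(0, np * k, np * k)
  sgn <- function(pair, case) if (pair[1] == case) 1 else -1
  for (i in seq_len(np)) {
    for (j in i:np) {
      shared <- intersect(pairs[, i], pairs[, j])
      if (i != j && !shared_case_blocks) shared <- character(0)
      block <- matrix(0, k, k)
      for (case in shared) {
        block <- block +
          sgn(pairs[, i], case) * sgn(pairs[, j], case) *
          covs[[case]] / ens$n[[case]]
      }
      ri <- (i - 1) * k + seq_len(k)
      rj <- (j - 1) * k + seq_len(k)
      V[ri, rj] <- block
      if (i != j) V[rj, ri] <- t(block)
    }
  }
  stats::cov2cor(V)
}

# B x q_total matrix of bootstrap replicate differences; cases resampled
# independently of each other, rows jointly within a case.
bootstrap_differences <- function(ens, B, seed = NULL) {
  k <- length(ens$variables)
  with_seed_if(seed, {
    case_means <- lapply(names(ens$x), function(nm) {
      m <- ens$x[[nm]][, ens$variables, drop = FALSE]
      n <- nrow(m)
      idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
      out <- matrix(NA_real_, B, k)
      for (j in seq_len(k)) out[, j] <- rowMeans(matrix(m[, j][idx], B, n))
      out
    })
    names(case_means) <- names(ens$x)
    pairs <- utils::combn(names(ens$x), 2)
    do.call(cbind, lapply(seq_len(ncol(pairs)), function(i) {
      case_means[[pairs[1, i]]] - case_means[[pairs[2, i]]]
    }))
  })
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf(
    "<comparison_set> %s: %d comparisons (%d pairs x %d variables), global level %s\n",
    x$method, x$q_total, x$n_pairs, length(x$variables),
    if (is.na(x$simultaneous_level)) "uncorrected" else format(x$simultaneous_level)))
  cat(sprintf("  significant differences: %d / %d\n",
              sum(x$comparisons$significant), x$q_total))
  print(x$comparisons, n = 6)
  invisible(x)
}

#' Tidy a comparison set
#'
#' @param x A `comparison_set`.
#' @param ... Unused.
#' @return A tibble with one row per (case pair, variable): `case_a`,
#'   `case_b`, `variable`, `diff`, `se`, `lower`, `upper`, `significant`,
#'   `method`.
#' @method tidy comparison_set
#' @export
tidy.comparison_set <- function(x, ...) {
  out <- x$comparisons
  out$method <- x$method
  out
}

#' One-row summary of a comparison set
#'
#' @param x A `comparison_set`.
#' @param ... Unused.
#' @method glance comparison_set
#' @export
glance.comparison_set <- function(x, ...) {
  tibble(
    method = x$method, n_cases = length(x$cases), n_pairs = x$n_pairs,
    n_variables = length(x$variables), q_total = x$q_total,
    alpha_s = x$alpha_s, simultaneous_level = x$simultaneous_level,
    n_significant = sum(x$comparisons$significant)
  )
}

#' Interval plot of mean differences, one panel per case pair
#'
#' @param object A `comparison_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_set
#' @export
autoplot.comparison_set <- function(object, ...) {
  d <- tidy(object)
  d$pair <- paste(d$case_a, "vs", d$case_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable, y = .data$diff,
                                  colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             shape = 18) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      name = "excludes 0") +
    ggplot2::labs(x = NULL, y = "difference in means",
                  title = sprintf("%s mean-difference intervals (%d comparisons)",
                                  object$method, object$q_total)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Write a comparison table to TSV
#'
#' @param comparison_set A `comparison_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparison_set, path) {
  stopifnot(inherits(comparison_set, "comparison_set"))
  tab <- tidy(comparison_set)[, c("case_a", "case_b", "variable", "diff",
                                  "lower", "upper", "significant")]
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
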