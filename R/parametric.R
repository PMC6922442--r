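#' Univariate t-based confidence intervals
#'
#' Classic per-variable intervals `mean_j +/- t_{n-1, 1-alpha/2} s_j / sqrt(n)`
#' with no correction for inspecting many variables at once. Their joint
#' (family-wise) coverage collapses as the number of variables grows — see
#' [uncorrected_simultaneous_coverage()] — which is why the simultaneous
#' constructions below exist; the univariate intervals are retained as the
#' uncorrected baseline.
#'
#' @param data Ensemble data frame (n models by p variables).
#' @param alpha Per-variable error level; the per-variable coverage is
#'   `1 - alpha`. Default 0.05.
#' @param quantiles `"t"` (default) for the t distribution with n-1 degrees of
#'   freedom, `"z"` for the normal approximation (indistinguishable at large n).
#' @return A `ci_set`. Its `simultaneous_level` is reported as
#'   `(1 - alpha)^p`, the family-wise coverage under independence, purely as a
#'   diagnostic.
#' @export
univariate_ci <- function(data, alpha = 0.05, quantiles = c("t", "z")) {
  quantiles <- match.arg(quantiles)
  stopifnot(alpha > 0, alpha < 1)
  x <- validate_ensemble(data)
  n <- nrow(x); p <- ncol(x)
  crit <- if (quantiles == "t") qt(1 - alpha / 2, df = n - 1) else qnorm(1 - alpha / 2)
  m <- colMeans(x)
  half <- crit * apply(x, 2, sd) / sqrt(n)
  new_ci_set(
    tibble(variable = colnames(x), mean = m, lower = m - half, upper = m + half),
    method = "univariate", alpha_s = NA_real_, alpha = alpha, n = n,
    simultaneous_level = (1 - alpha)^p, critical_value = crit
  )
}

#' Family-wise coverage of uncorrected intervals under independence
#'
#' If p independent variables each receive a `1 - alpha` interval, the chance
#' that all p intervals cover simultaneously is `(1 - alpha)^p`. At p in the
#' hundreds this is essentially zero, so at least one population mean is
#' almost surely missed.
#'
#' @param alpha Per-variable error level in (0, 1).
#' @param p Number of variables.
#' @return The probability `(1 - alpha)^p`.
#' @examples
#' uncorrected_simultaneous_coverage(0.025, 2)  # 0.951
#' uncorrected_simultaneous_coverage(0.05, 275) # ~ 0
#' @export
uncorrected_simultaneous_coverage <- function(alpha, p) {
  stopifnot(alpha > 0, alpha < 1, p >= 1)
  (1 - alpha)^p
}

#' Bonferroni simultaneous confidence intervals
#'
#' Guarantees family-wise coverage at least `1 - alpha_s` regardless of the
#' dependence between variables by building each per-variable interval at
#' level `alpha = alpha_s / p`. Each interval taken individually is therefore
#' conservative (`1 - alpha > 1 - alpha_s`); under dependence the whole set is
#' conservative too.
#'
#' @inheritParams univariate_ci
#' @param alpha_s Simultaneous (family-wise) error level; default 0.05.
#' @return A `ci_set` with `simultaneous_level = 1 - alpha_s`.
#' @export
bonferroni_ci <- function(data, alpha_s = 0.05, quantiles = c("t", "z")) {
  quantiles <- match.arg(quantiles)
  stopifnot(alpha_s > 0, alpha_s < 1)
  x <- validate_ensemble(data)
  n <- nrow(x); p <- ncol(x)
  alpha <- alpha_s / p
  crit <- if (quantiles == "t") qt(1 - alpha / 2, df = n - 1) else qnorm(1 - alpha / 2)
  if (!is.finite(crit) || alpha <= 0) {
    abort(paste0(
      "alpha_s / p underflowed; the corrected level is numerically zero. ",
      "Reduce p (e.g. preselect variables) or raise alpha_s."),
      class = "emci_validation_error")
  }
  m <- colMeans(x)
  half <- crit * apply(x, 2, sd) / sqrt(n)
  new_ci_set(
    tibble(variable = colnames(x), mean = m, lower = m - half, upper = m + half),
    method = "bonferroni", alpha_s = alpha_s, alpha = alpha, n = n,
    simultaneous_level = 1 - alpha_s, critical_value = crit
  )
}

#' Sample correlation matrix of an ensemble
#'
#' Pearson correlation of the observations, with a projection to the nearest
#' positive-semidefinite matrix (eigenvalue clipping at zero, diagonal
#' re-normalized to one) if sampling noise pushed an eigenvalue negative. In
#' the intended regime n >> p the repair is almost never triggered.
#'
#' @param data Ensemble data frame with at least 3 rows and no constant columns.
#' @return A p x p correlation matrix.
#' @export
estimate_correlation <- function(data) {
  x <- validate_ensemble(data, min_rows = 3)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-SD column(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", "),
                 ". Run filter_low_variance() first."),
          class = "emci_validation_error")
  }
  r <- cor(x)
  eig <- eigen(r, symmetric = TRUE)
  if (min(eig$values) < 0) {
    r <- eig$vectors %*% (pmax(eig$values, 0) * t(eig$vectors))
    r <- stats::cov2cor((r + t(r)) / 2)
  }
  dimnames(r) <- list(colnames(x), colnames(x))
  r
}

#' Equicoordinate quantile of a correlated multivariate normal
#'
#' The critical value `c` such that a vector Z ~ N_p(0, Gamma) satisfies
#' `max_j |Z_j| <= c` with probability `1 - alpha_s`. Estimated by Monte Carlo:
#' the empirical `1 - alpha_s` quantile of `max_j |Z_j|` over `M` draws. Under
#' an identity Gamma this converges to the Sidak closed form
#' `qnorm((1 + (1 - alpha_s)^(1/p)) / 2)`; under total dependence it collapses
#' to the univariate `qnorm(1 - alpha_s / 2)`.
#'
#' @param corr p x p correlation matrix (e.g. from [estimate_correlation()]).
#' @param alpha_s Simultaneous error level.
#' @param M Number of Monte Carlo draws; default 1e5.
#' @param seed Optional integer seed making the quantile reproducible.
#' @return The scalar critical value.
#' @export
exact_normal_quantile <- function(corr, alpha_s = 0.05, M = 1e5, seed = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr), alpha_s > 0, alpha_s < 1,
            M >= 10000)
  p <- ncol(corr)
  with_seed_if(seed, {
    z <- rmvnorm_chol(M, corr)
    u <- abs(z[, 1])
    if (p > 1) for (j in 2:p) u <- pmax(u, abs(z[, j]))
    quantile(u, 1 - alpha_s, names = FALSE, type = 7)
  })
}

#' Exact-normal simultaneous confidence intervals
#'
#' Replaces the Bonferroni critical value by the equicoordinate quantile of
#' N_p(0, Gamma-hat), where Gamma-hat is the estimated correlation matrix of
#' the observations. The intervals are `mean_j +/- c s_j / sqrt(n)`; because
#' the quantile accounts for the dependence between variables, they are never
#' wider than the Bonferroni ones (up to Monte Carlo noise) and can be
#' markedly narrower under strong correlation.
#'
#' @inheritParams bonferroni_ci
#' @param M Monte Carlo draws for the quantile; default 1e5.
#' @param seed Optional integer seed.
#' @return A `ci_set`.
#' @export
exact_normal_ci <- function(data, alpha_s = 0.05, M = 1e5, seed = NULL) {
  x <- validate_ensemble(data, min_rows = 3)
  n <- nrow(x)
  corr <- estimate_correlation(x)
  crit <- exact_normal_quantile(corr, alpha_s = alpha_s, M = M, seed = seed)
  m <- colMeans(x)
  half <- crit * apply(x, 2, sd) / sqrt(n)
  new_ci_set(
    tibble(variable = colnames(x), mean = m, lower = m - half, upper = m + half),
    method = "exact_normal", alpha_s = alpha_s, alpha = alpha_s, n = n,
    simultaneous_level = 1 - alpha_s, seed = seed, M = M, critical_value = crit
  )
}
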