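#' Bonferroni sample-size calculation for a target margin of error
#'
#' Of the simultaneous constructions, only the Bonferroni interval has an
#' explicit closed form in n, so it is the one that yields an a-posteriori
#' sample-size formula: to make every half-width at most `margin` when `p_or_q`
#' quantities are corrected for simultaneously,
#' `n = ceil( (z_{1 - alpha_s/(2 p_or_q)} * max_j sd_j / margin)^2 )`.
#' The SDs must be guessed or estimated from the data already in hand; for
#' mean-difference margins pass the per-comparison difference SDs from
#' [comparison_sds()].
#'
#' @param sds Estimated standard deviations, one per variable (or per
#'   comparison difference).
#' @param margin Target maximal margin of error (CI half-width), > 0.
#' @param alpha_s Simultaneous error level; default 0.05.
#' @param p_or_q Number of quantities corrected for; defaults to
#'   `length(sds)`.
#' @return Required number of models per ensemble (integer).
#' @examples
#' bonferroni_sample_size(1, margin = 0.1, alpha_s = 0.05)  # 385
#' @export
bonferroni_sample_size <- function(sds, margin, alpha_s = 0.05,
                                   p_or_q = length(sds)) {
  stopifnot(is.numeric(sds), length(sds) >= 1, all(sds >= 0),
            margin > 0, alpha_s > 0, alpha_s < 1, p_or_q >= 1)
  if (all(sds == 0)) {
    warn("All SDs are zero; any sample size achieves the margin. Returning 1.")
    return(1L)
  }
  z <- qnorm(1 - alpha_s / (2 * p_or_q))
  as.integer(ceiling((z * max(sds) / margin)^2))
}

#' Per-comparison difference standard deviations
#'
#' For every unordered pair of cases and every variable, the standard
#' deviation of a single-model difference, `sqrt(s2_A + s2_B)` — the quantity
#' whose `/sqrt(n)` scaling (equal per-case n) sets the width of a
#' mean-difference interval.
#'
#' @inheritParams pairwise_differences
#' @return A tibble with columns `case_a`, `case_b`, `variable`, `sd_diff`.
#' @export
comparison_sds <- function(ensembles, variables = NULL) {
  ens <- check_cases(ensembles, variables)
  pairs <- utils::combn(names(ens$x), 2)
  dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(case_a = a, case_b = b, variable = ens$variables,
           sd_diff = unname(sqrt(ens$vars[[a]] + ens$vars[[b]])))
  }))
}
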