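#' Toy unbranched metabolic pathway
#'
#' A linear chain of `r` enzymatic reactions connected by `r - 1` internal
#' metabolites (boundary species omitted): reaction j consumes metabolite
#' j - 1 and produces metabolite j. The reference steady-state flux is one
#' through every reaction, so the stoichiometry times the flux vector is zero
#' by construction. This is the minimal network on which metabolic control
#' analysis is exact, and it serves as the known-structure stand-in for a
#' genome-derived kinetic model when generating flux-control-coefficient
#' ensembles.
#'
#' @param r Number of reactions, at least 2.
#' @return A `toy_network`: list with `stoichiometry` ((r-1) x r integer
#'   matrix of full row rank), `reference_flux` (all ones), `reaction_names`
#'   (`R1..Rr`) and `metabolite_names` (`M1..M(r-1)`).
#' @examples
#' build_linear_pathway(3)$stoichiometry
#' @export
build_linear_pathway <- function(r) {
  stopifnot(r >= 2)
  m <- r - 1
  N <- matrix(0L, m, r)
  for (i in seq_len(m)) {
    N[i, i] <- 1L       # produced by reaction i
    N[i, i + 1] <- -1L  # consumed by reaction i + 1
  }
  structure(
    list(
      stoichiometry = N,
      reference_flux = rep(1, r),
      reaction_names = paste0("R", seq_len(r)),
      metabolite_names = paste0("M", seq_len(m))
    ),
    class = "toy_network"
  )
}

#' @export
print.toy_network <- function(x, ...) {
  cat(sprintf("<toy_network> linear pathway: %d reactions, %d internal metabolites\n",
              length(x$reaction_names), length(x$metabolite_names)))
  invisible(x)
}

#' Sample scaled elasticities for a toy network
#'
#' Scaled elasticities are the log-log sensitivities of reaction rates to
#' metabolite concentrations. For each participating (reaction, metabolite)
#' pair a value is drawn uniformly: substrate elasticities in (0, 1) (drawn as
#' `1 - U(0,1)`), product elasticities in (-1, 0); non-participating entries
#' are exactly zero. This mimics parameter-space sampling over unknown enzyme
#' saturation states.
#'
#' @param net A [build_linear_pathway()] network.
#' @param seed Optional integer seed.
#' @return An r x m elasticity matrix (rows = reactions, columns =
#'   metabolites).
#' @export
sample_elasticities <- function(net, seed = NULL) {
  stopifnot(inherits(net, "toy_network"))
  r <- length(net$reaction_names)
  m <- length(net$metabolite_names)
  with_seed_if(seed, {
    E <- matrix(0, r, m, dimnames = list(net$reaction_names, net$metabolite_names))
    for (j in seq_len(r)) {
      if (j >= 2) E[j, j - 1] <- 1 - runif(1)   # substrate of reaction j
      if (j <= m) E[j, j] <- -runif(1)          # product of reaction j
    }
    E
  })
}

#' Flux control coefficients from stoichiometry and elasticities
#'
#' Computes the scaled flux-control matrix
#' `C = I - E (N D_v E)^{-1} N D_v`, where `N` is the stoichiometry, `E` the
#' scaled elasticity matrix and `D_v = diag(reference_flux)`. Row i gives the
#' fold change of flux i under a fractional perturbation of each enzyme's
#' activity. Two algebraic identities serve as exactness oracles: the rows sum
#' to one (summation theorem, a consequence of `N v = 0`) and `C E = 0`
#' (connectivity theorem).
#'
#' @param net A [build_linear_pathway()] network.
#' @param elasticity Elasticity matrix from [sample_elasticities()].
#' @param cond_tol Reciprocal-condition threshold: draws whose Jacobian
#'   `N D_v E` has condition number above this are rejected as unstable
#'   (condition of class `emci_unstable_model`), signalling the caller to
#'   redraw. Default 1e8.
#' @return An r x r FCC matrix (rows = controlled fluxes, columns = perturbed
#'   enzymes).
#' @export
compute_fcc <- function(net, elasticity, cond_tol = 1e8) {
  stopifnot(inherits(net, "toy_network"))
  N <- net$stoichiometry
  Dv <- diag(net$reference_flux, nrow = length(net$reference_flux))
  r <- ncol(N)
  jac <- N %*% Dv %*% elasticity
  kap <- tryCatch(kappa(jac, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > cond_tol) {
    abort("Jacobian N D_v E is singular or ill-conditioned; redraw elasticities.",
          class = "emci_unstable_model")
  }
  C <- diag(r) - elasticity %*% solve(jac, N %*% Dv)
  dimnames(C) <- list(net$reaction_names, net$reaction_names)
  C
}

#' Generate a synthetic ensemble of flux control coefficients
#'
#' Emulates ensemble modeling on the toy pathway: elasticities are sampled
#' repeatedly, each accepted (well-conditioned) draw yields an FCC matrix, and
#' the row for the target flux becomes one model's p = r variables. The
#' resulting marginals are ratios of random quantities — skewed, heavy-tailed
#' and mutually correlated, the data shape that motivates the bootstrap
#' intervals — while every row still sums to one exactly (summation theorem).
#'
#' @param net A [build_linear_pathway()] network.
#' @param target_reaction Index or name of the controlled flux; default 1.
#' @param n_models Number of accepted models; at least 2.
#' @param seed Optional integer seed.
#' @param cond_tol Passed to [compute_fcc()].
#' @return A tibble with `n_models` rows and one column per reaction, named by
#'   reaction; the number of rejected draws is attached as attribute
#'   `"rejections"` and the case label as `"case_label"`.
#' @export
generate_fcc_ensemble <- function(net, target_reaction = 1, n_models,
                                  seed = NULL, cond_tol = 1e8) {
  stopifnot(inherits(net, "toy_network"), n_models >= 2)
  r <- length(net$reaction_names)
  if (is.character(target_reaction)) {
    target_reaction <- match(target_reaction, net$reaction_names)
  }
  stopifnot(!is.na(target_reaction), target_reaction >= 1, target_reaction <= r)
  with_seed_if(seed, {
    out <- matrix(NA_real_, n_models, r,
                  dimnames = list(NULL, net$reaction_names))
    accepted <- 0L; attempts <- 0L
    while (accepted < n_models) {
      attempts <- attempts + 1L
      E <- sample_elasticities(net)
      C <- tryCatch(compute_fcc(net, E, cond_tol = cond_tol),
                    emci_unstable_model = function(e) NULL)
      if (is.null(C)) {
        if (attempts >= 200L && accepted < attempts / 100) {
          abort(sprintf(
            "Acceptance rate below 1%% (%d accepted in %d draws); the network or condition tolerance is unworkable.",
            accepted, attempts),
            class = "emci_generation_error")
        }
        next
      }
      accepted <- accepted + 1L
      out[accepted, ] <- C[target_reaction, ]
    }
    res <- as_tibble(as.data.frame(out))
    attr(res, "rejections") <- attempts - accepted
    attr(res, "case_label") <- sprintf("fcc_%s", net$reaction_names[target_reaction])
    res
  })
}
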