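test_that("the linear pathway is at steady state with full-rank stoichiometry", {
  net <- build_linear_pathway(3)
  expect_equal(unname(net$stoichiometry),
               matrix(c(1, 0, -1, 1, 0, -1), 2, 3), ignore_attr = TRUE)
  expect_equal(drop(net$stoichiometry %*% net$reference_flux), c(0, 0))

  tiny <- build_linear_pathway(2)
  expect_equal(nrow(tiny$stoichiometry), 1L)

  for (r in c(2, 5, 12)) {
    N <- build_linear_pathway(r)$stoichiometry
    expect_equal(qr(N)$rank, r - 1L)
    expect_equal(drop(N %*% rep(1, r)), rep(0, r - 1))
  }
})

test_that("sampled elasticities respect the participation pattern and sign ranges", {
  net <- build_linear_pathway(6)
  participation <- outer(1:6, 1:5, function(j, i) i == j - 1 | i == j)
  withr::with_seed(91, {
    ok <- vapply(1:1000, function(i) {
      E <- sample_elasticities(net)
      sub <- E[cbind(2:6, 1:5)]   # substrate entries
      prod <- E[cbind(1:5, 1:5)]  # product entries
      all(E[!participation] == 0) &&
        all(sub > 0 & sub < 1) && all(prod < 0 & prod > -1)
    }, logical(1))
    expect_true(all(ok))
  })
  expect_identical(sample_elasticities(net, seed = 92),
                   sample_elasticities(net, seed = 92))
})

test_that("summation and connectivity theorems hold for every accepted draw", {
  net <- build_linear_pathway(6)
  withr::with_seed(93, {
    worst_sum <- 0; worst_conn <- 0
    for (i in 1:100) {
      E <- sample_elasticities(net)
      C <- tryCatch(compute_fcc(net, E),
                    emci_unstable_model = function(e) NULL)
      if (is.null(C)) next
      worst_sum <- max(worst_sum, max(abs(rowSums(C) - 1)))
      worst_conn <- max(worst_conn, max(abs(C %*% E)))
    }
    expect_lt(worst_sum, 1e-8)
    expect_lt(worst_conn, 1e-8)
  })
})

test_that("control coefficients match a finite-difference perturbation oracle", {
  # Two-step pathway with power-law kinetics v1 = e1 * M^eps1 (eps1 < 0,
  # product), v2 = e2 * M^eps2 (eps2 > 0, substrate). The steady-state flux
  # responds to enzyme perturbations as J(e1, e2); central log-log finite
  # differences of the numerically solved steady state give the FCCs.
  net <- build_linear_pathway(2)
  E <- sample_elasticities(net, seed = 95)
  eps1 <- E[1, 1]; eps2 <- E[2, 1]
  C <- compute_fcc(net, E)

  flux_at <- function(e1, e2) {
    # solve e1 M^eps1 = e2 M^eps2 for the steady-state metabolite M
    M <- uniroot(function(m) e1 * m^eps1 - e2 * m^eps2,
                 lower = 1e-8, upper = 1e8, tol = 1e-14)$root
    e1 * M^eps1
  }
  h <- 1e-5
  fd_e1 <- (log(flux_at(exp(h), 1)) - log(flux_at(exp(-h), 1))) / (2 * h)
  fd_e2 <- (log(flux_at(1, exp(h))) - log(flux_at(1, exp(-h)))) / (2 * h)
  expect_equal(C[1, 1], fd_e1, tolerance = 1e-6)
  expect_equal(C[1, 2], fd_e2, tolerance = 1e-6)
  # closed form for this chain: C_e1 = eps2 / (eps2 - eps1)
  expect_equal(C[1, 1], eps2 / (eps2 - eps1), tolerance = 1e-10)
})

test_that("FCC ensembles inherit the summation theorem and show marginal skew", {
  net <- build_linear_pathway(10)
  ens <- generate_fcc_ensemble(net, target_reaction = 1, n_models = 2000,
                               seed = 96)
  expect_equal(dim(ens), c(2000L, 10L))
  expect_lt(max(abs(rowSums(as.matrix(ens)) - 1)), 1e-8)
  skews <- apply(as.matrix(ens), 2, sample_skewness)
  expect_gt(max(abs(skews)), 0.5)   # heavy-tailed marginals motivate BootCI
  expect_identical(
    as.matrix(generate_fcc_ensemble(net, 1, 50, seed = 97)),
    as.matrix(generate_fcc_ensemble(net, 1, 50, seed = 97)))
})

test_that("copula ensembles hit their true means, SDs, correlation and skew", {
  # identity-transform case: normal marginals keep the latent correlation
  corr <- exch_corr(4, 0.5)
  spec <- copula_spec(c(-1, 0, 1, 2), rep(2, 4), correlation = corr)
  big <- generate_copula_ensemble(spec, 20000, seed = 98)
  expect_lt(max(abs(stats::cor(as.matrix(big)) - corr)), 3 / sqrt(20000) + 0.02)
  expect_true(all(abs(colMeans(as.matrix(big)) - spec$true_means) <=
                    4 * 2 / sqrt(20000)))

  sk <- generate_copula_ensemble(
    copula_spec(0, 1, marginals = "lognormal_shifted", skew = 2), 5000,
    seed = 99)
  expect_gt(sample_skewness(sk[[1]]), 0.5)
  neg <- generate_copula_ensemble(
    copula_spec(0, 1, marginals = "gamma_shifted", skew = -1.5), 5000,
    seed = 100)
  expect_lt(sample_skewness(neg[[1]]), -0.5)
})

test_that("the coverage harness reproduces the closed-form uncorrected coverage", {
  spec <- copula_spec(rep(0, 20), rep(1, 20))
  rep_ <- run_coverage_experiment(spec, method = "univariate", alpha_s = 0.05,
                                  n = 200, reps = 500, seed = 102)
  expected <- 0.95^20                      # ~ 0.358 under independence
  mc3 <- 3 * sqrt(expected * (1 - expected) / 500)
  expect_lt(abs(rep_$simultaneous_coverage - expected), mc3 + 0.02)
  # rate bookkeeping: coverage + left miss + right miss = 1 per variable
  tv <- tidy(rep_)
  expect_equal(tv$coverage + tv$miss_left + tv$miss_right, rep(1, 20))
})
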