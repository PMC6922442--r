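test_that("top-variable preselection reproduces the case-study bookkeeping", {
  cases <- make_four_cases()
  cisets <- lapply(cases, balanced_simultaneous_ci, B = 1000, seed = 61)
  sel <- preselect_top_variables(cisets)          # default k = 7
  expect_length(sel, 15L)                          # union of per-case top 7
  expect_equal(sel, sprintf("V%02d", 1:15))

  cmp <- compare_cases(cases, variables = sel, method = "bonferroni")
  expect_equal(cmp$n_pairs, 6L)                    # C(4, 2)
  expect_equal(cmp$q_total, 90L)                   # 15 x 6, corrected globally
  expect_equal(nrow(tidy(cmp)), 90L)
})

test_that("preselection keeps all variables when k exceeds p and warns when empty", {
  ens <- make_four_cases(n = 300)[["A"]][, 1:5]
  cs <- balanced_simultaneous_ci(ens, B = 500, seed = 62)
  expect_setequal(preselect_top_variables(list(cs), k = 50), names(ens))

  null_ens <- make_normal_ensemble(n = 200, p = 3, seed = 63)
  null_cs <- bonferroni_ci(null_ens)
  expect_warning(sel <- preselect_top_variables(list(null_cs)), "empty")
  expect_length(sel, 0L)
})

test_that("pairwise differences match hand arithmetic on two tiny cases", {
  a <- tibble::tibble(v = c(1, 3))   # mean 2, var 2
  b <- tibble::tibble(v = c(4, 8))   # mean 6, var 8
  d <- pairwise_differences(list(A = a, B = b))
  expect_equal(d$diff, 2 - 6)
  expect_equal(d$se, sqrt(2 / 2 + 8 / 2))
  expect_equal(nrow(pairwise_differences(make_four_cases(n = 50))), 6L * 20L)
})

test_that("identical cases produce zero differences covered by every method", {
  ens <- make_normal_ensemble(n = 150, p = 4, seed = 64)
  twin <- list(A = ens, B = ens)
  d <- pairwise_differences(twin)
  expect_true(all(d$diff == 0))
  for (m in c("univariate", "bonferroni", "exact_normal", "bootstrap")) {
    cmp <- compare_cases(twin, method = m, B = 500, M = 1e4, seed = 65)
    expect_false(any(cmp$comparisons$significant))
    expect_true(all(cmp$comparisons$lower <= 0 & cmp$comparisons$upper >= 0))
  }
})

test_that("swapping pair orientation negates the difference and mirrors the CI", {
  cases <- make_four_cases(n = 100)[c("A", "B")]
  fwd <- compare_cases(cases, method = "bonferroni")$comparisons
  rev <- compare_cases(cases[c("B", "A")], method = "bonferroni")$comparisons
  expect_equal(rev$diff, -fwd$diff)
  expect_equal(rev$lower, -fwd$upper)
  expect_equal(rev$upper, -fwd$lower)
})

test_that("a missing variable in one case is an error", {
  cases <- make_four_cases(n = 50)
  cases$B <- cases$B[, 1:10]
  expect_error(compare_cases(cases, variables = sprintf("V%02d", 1:15),
                             method = "bonferroni"),
               class = "emci_validation_error")
})

test_that("the uncorrected method flags at least as many comparisons as any corrected one", {
  cases <- make_four_cases(n = 120, seed = 66)
  vars <- sprintf("V%02d", 1:15)
  counts <- vapply(
    c("univariate", "bonferroni", "exact_normal", "bootstrap"),
    function(m) {
      cmp <- compare_cases(cases, variables = vars, method = m,
                           B = 8000, M = 2e4, seed = 67)
      sum(cmp$comparisons$significant)
    },
    integer(1))
  expect_true(all(counts["univariate"] >= counts[-1]))
})

test_that("exact-normal comparisons honour shared-case correlation blocks", {
  cases <- make_four_cases(n = 100)[c("A", "B", "C")]
  vars <- c("V01", "V02")
  shared <- compare_cases(cases, variables = vars, method = "exact_normal",
                          M = 2e4, seed = 68, shared_case_blocks = TRUE)
  exch <- compare_cases(cases, variables = vars, method = "exact_normal",
                        M = 2e4, seed = 68, shared_case_blocks = FALSE)
  expect_equal(shared$q_total, 6L)
  expect_equal(exch$q_total, 6L)
  # same point estimates, potentially different critical values
  expect_equal(shared$comparisons$diff, exch$comparisons$diff)
  expect_true(is.finite(shared$critical_value) && is.finite(exch$critical_value))
})

test_that("family-wise error over true-null comparisons stays at the nominal level", {
  # three cases drawn from the same distribution: every comparison is null
  spec <- make_skewed_spec(p = 3)
  reps <- 200
  fwer <- c(bonferroni = 0, bootstrap = 0)
  withr::with_seed(71, {
    for (i in seq_len(reps)) {
      cases <- list(A = generate_copula_ensemble(spec, 150),
                    B = generate_copula_ensemble(spec, 150),
                    C = generate_copula_ensemble(spec, 150))
      for (m in names(fwer)) {
        cmp <- compare_cases(cases, method = m, alpha_s = 0.05, B = 1000)
        fwer[m] <- fwer[m] + any(cmp$comparisons$significant)
      }
    }
  })
  fwer <- fwer / reps
  mc3 <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lte(fwer[["bonferroni"]], 0.05 + mc3)
  expect_lte(fwer[["bootstrap"]], 0.05 + mc3)
})
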