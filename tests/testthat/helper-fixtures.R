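# Fixtures are generated in code; no data files.

# Independent-normal ensemble with named columns.
make_normal_ensemble <- function(n = 200, p = 5, seed = 1, mean = 0, sd = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p, mean, sd), n, p)
    colnames(x) <- sprintf("V%02d", seq_len(p))
    tibble::as_tibble(as.data.frame(x))
  })
}

# Exchangeable-correlation matrix.
exch_corr <- function(p, rho) {
  r <- matrix(rho, p, p); diag(r) <- 1; r
}

# Four synthetic cases emulating alternative operational configurations of
# the same network. 20 variables; each case has 7 planted large-mean
# variables (SD 1, means 4..10) and 13 null variables, arranged so the union
# of per-case top-7 significant selections is exactly variables 1..15:
#   case A -> 1..7, case B -> 8..14, case C -> 15 and 1..6, case D -> 1..7.
make_four_cases <- function(n = 400, seed = 42) {
  sets <- list(A = 1:7, B = 8:14, C = c(15, 1:6), D = 1:7)
  withr::with_seed(seed, {
    lapply(sets, function(idx) {
      mu <- rep(0, 20)
      mu[idx] <- seq(10, 4, length.out = length(idx))
      x <- matrix(rnorm(n * 20), n, 20)
      x <- sweep(x, 2, mu, "+")
      colnames(x) <- sprintf("V%02d", 1:20)
      tibble::as_tibble(as.data.frame(x))
    })
  })
}

# Known-truth skewed copula spec used across bootstrap coverage tests:
# mixed-direction gamma/lognormal marginals with moderate correlation.
make_skewed_spec <- function(p = 5) {
  copula_spec(
    true_means = rep(0, p),
    sds = rep(1, p),
    correlation = exch_corr(p, 0.3),
    marginals = rep(c("gamma_shifted", "lognormal_shifted"), length.out = p),
    skew = rep(c(1.5, -1.5, 2, 1, -1), length.out = p)
  )
}

# Sample skewness (biased moment estimator is fine for sign/size checks).
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
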