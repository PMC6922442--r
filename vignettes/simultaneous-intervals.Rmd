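---
title: "Simultaneous confidence intervals for populations of model outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous confidence intervals for populations of model outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emci)
```

## The inference problem

Ensemble modeling of metabolism yields an $n \times p$ matrix of model
outputs: $n$ kinetic models, each a different parameter set consistent with
the same observed steady state, evaluated on $p$ variables — typically the
flux control coefficients (FCCs) of a target flux. The estimand for variable
$j$ is its population mean $\mu_j$, the limit of the sample mean as the
ensemble grows. A confidence interval at level $1-\alpha$ contains $\mu_j$
in a fraction $1-\alpha$ of hypothetical repetitions of the whole sampling
exercise; checking whether the interval contains zero is the dual of testing
$\mu_j = 0$.

The difficulty is multiplicity. If each of $p$ independent variables gets
its own $1-\alpha$ interval, the probability that *all* intervals cover is
$(1-\alpha)^p$ — `uncorrected_simultaneous_coverage()` — which at
$\alpha = 0.05$ and $p$ in the hundreds is numerically zero. Any ranking or
screening exercise that reads all $p$ intervals at once therefore needs
*simultaneous* intervals, calibrated so the family-wise coverage is
$1-\alpha_S$.

## The four constructions

**Univariate (baseline).** $\bar{x}_j \pm t_{n-1,1-\alpha/2}\, s_j/\sqrt n$.
Kept as the reference point that the corrected methods are judged against;
its reported `simultaneous_level` of $(1-\alpha)^p$ is a diagnostic, not a
guarantee.

**Bonferroni (BCI).** Each variable's interval is built at
$\alpha = \alpha_S/p$. By the union bound the family-wise coverage is at
least $1-\alpha_S$ under *any* dependence; under positive dependence it is
conservative (wider than necessary). Each interval taken individually runs
at the elevated level $1-\alpha_S/p$.

**Exact normal (ENCI).** The critical value is the equicoordinate quantile
$c$ of $N_p(0,\hat\Gamma)$ — the value such that
$\Pr(\max_j |Z_j| \le c) = 1-\alpha_S$ — with $\hat\Gamma$ the sample
correlation of the observations; intervals are
$\bar{x}_j \pm c\, s_j/\sqrt n$. Because $c$ accounts for dependence, ENCI
is never wider than BCI (at independence it reduces to the Šidák value
$\Phi^{-1}((1+(1-\alpha_S)^{1/p})/2)$, already slightly below Bonferroni's
$z_{1-\alpha_S/2p}$) and can be much narrower under strong correlation. Its
assumptions: approximate normality of the sample means (safe at ensemble
sizes in the thousands) and a stable correlation estimate ($n \gg p$).

**Balanced bootstrap (BootCI).** Drops the normality/symmetry assumption.
$B$ with-replacement resamples of the $n$ rows (rows resampled jointly, so
the dependence between variables is preserved) give a $B \times p$ matrix of
resampled means. Each column is pre-pivoted through its own ECDF as
fractional midranks $r_{bj} = \mathrm{rank}(\bar{x}^*_{bj})/(B+1)$, putting
every variable on a common uniform scale whatever its marginal shape. The
balance statistic $u_b = \max_j \max(r_{bj},\, 1-r_{bj})$ tracks each
replicate's most extreme coordinate; the empirical $1-\alpha_S$ quantile $q$
of $\{u_b\}$, clipped to $[1/2,\, B/(B+1)]$, is the single cutoff used for
every variable and both tails. The interval for variable $j$ is
$[Q_j(1-q),\, Q_j(q)]$, the empirical quantiles of its resampled means. One
shared $q$ delivers the three guarantees at once: nominal simultaneous
coverage (the max over variables), equal marginal coverages (same $q$ for
all $j$), and tail balance (out-probability $1-q$ on each side). With skewed
marginals the two arms differ in length, the long arm following the data's
long tail.

The construction uses raw mean roots with the ECDF as the pre-pivot;
studentized roots are a known alternative but are deliberately not used —
the raw-mean version keeps the single-$q$ balance property exact in the
bootstrap world and needs no variance re-estimation per replicate.

### Width and flag orderings

On any dataset the per-variable widths order univariate ≤ ENCI ≤ BCI (the
ENCI/BCI comparison up to Monte Carlo noise in $c$), hence the uncorrected
method always flags at least as many variables, and at least as many
case differences, as any corrected method. The test suite asserts both
orderings on independent, correlated, and FCC-ensemble fixtures. For the
ordering check univariate and Bonferroni are computed with normal quantiles
(`quantiles = "z"`), since ENCI is normal-based by definition; at the
ensemble sizes the package targets, $t$ versus $z$ is far below every other
source of uncertainty.

## Comparing cases

Alternative steady-state configurations of the same network ("cases") are
compared through intervals for differences of means,
$d = \bar{x}_{A,j} - \bar{x}_{B,j}$ with standard error
$\sqrt{s^2_{A,j}/n_A + s^2_{B,j}/n_B}$, over every unordered case pair and
every selected variable. The simultaneity correction spans *all*
$q_{\mathrm{total}} = \binom{\#\text{cases}}{2} \times \#\text{variables}$
comparisons globally — never pair by pair — so significance statements hold
jointly across the whole comparison table. Difference intervals use $z$
quantiles throughout for internal consistency with the normal-based ENCI
construction.

For ENCI, comparisons sharing a case are correlated:
$\mathrm{Cov}(d^{AB}, d^{AC}) = \Sigma_A/n_A$ (sign-flipped when the shared
case changes sides). The default assembles these shared-case blocks from the
per-case sample covariances; `shared_case_blocks = FALSE` treats distinct
pairs as uncorrelated instead, for users who prefer the exchangeable
approximation. For the bootstrap, each case is resampled independently
within a replicate, all $q_{\mathrm{total}}$ differences recomputed, and the
balanced max-rank construction applied in the difference space.

`preselect_top_variables()` implements the screening step used before
case comparison: per case, the $k = 7$ (default) largest-|mean| variables
among those whose interval excludes zero, then the union across cases.

## Sample size

Only the Bonferroni interval has a closed width formula, so it carries the
a-posteriori sample-size calculation: for a target maximal margin of error
$E$ over $p$ (or $q_{\mathrm{total}}$) quantities,
$n = \lceil (z_{1-\alpha_S/2p} \cdot \max_j s_j / E)^2 \rceil$, with the
SDs estimated from the ensembles already in hand (for differences,
$s_j = \sqrt{s^2_{A,j} + s^2_{B,j}}$ at equal per-case $n$). The normal
quantile is used rather than $t$ because $n$ is the unknown; at the
resulting sizes the distinction is nil. The estimate inherits the
conservatism of Bonferroni and the noise of the pilot SDs, and is an
indication rather than a guarantee — the suite checks it by regenerating
data of the returned size and measuring the achieved margin, allowing for
SD re-estimation noise of order $1/\sqrt{2(n-1)}$.

## What the synthetic generators emulate

**Toy pathway FCC ensembles.** `build_linear_pathway(r)` is an unbranched
chain of $r$ reactions at a unit reference flux; sampled scaled elasticities
(substrates in $(0,1)$, products in $(-1,0)$, uniform) feed the scaled
control-coefficient formula
$C = I - E\,(N D_v E)^{-1} N D_v$. The scaled formulation makes the two
structural theorems exact algebraic identities — rows of $C$ sum to one
(summation theorem, from $Nv = 0$) and $CE = 0$ (connectivity theorem) —
which the tests assert to $10^{-8}$ on every accepted draw. Draws whose
Jacobian $N D_v E$ has condition number above $10^{8}$ are rejected and
redrawn, mirroring the practice of keeping only stable kinetic models; on
the linear chain rejections are rare. The resulting FCC marginals are ratios
of random quantities: skewed, heavy-tailed, and mutually correlated (the
summation constraint alone induces negative dependence) — the data shape
that motivates the bootstrap intervals. What the toy network does *not*
emulate: branched stoichiometry, conserved moieties, thermodynamic
constraints, or realistic kinetic rate laws. Passing tests demonstrate the
statistical machinery on data with the right moments and shape, not
biological fidelity of any particular network.

**Copula ensembles.** `copula_spec()` defines a Gaussian copula with
specified latent correlation and per-variable marginals (normal, shifted
lognormal, shifted gamma) parameterized directly by their target skewness,
then affinely standardized so each variable's true mean and SD are *exact*
in distribution. Known truth is what a coverage experiment needs: the
fraction of replicate datasets in which all intervals contain the true
means is the realized simultaneous coverage. The coverage fixtures used in
the test suite plant mixed-direction skews of magnitude 0.5–2 — the range a
modeler would call realistically skewed for control-coefficient data without
being pathological — with exchangeable latent correlation 0.3. Gaussian-copula
dependence cannot represent tail dependence; none of the guarantees tested
rely on it.

## Numerical choices

- **Sample SD** uses the $n-1$ denominator everywhere.
- **ENCI quantile** is Monte Carlo: the empirical $1-\alpha_S$ quantile of
  $\max_j |Z_j|$ over $M = 10^5$ (default) draws through a single
  `rnorm` stream, so one integer seed reproduces it exactly. Its Monte Carlo
  standard error — $\sqrt{\alpha_S(1-\alpha_S)/M}$ divided by the density of
  the max-statistic at the quantile — is about $0.005$ at
  $p = 10, M = 10^5$, negligible against sampling noise in the data.
- **Correlation repair**: if sampling noise makes $\hat\Gamma$ indefinite,
  eigenvalues are clipped at zero and the diagonal re-normalized; with
  $n \gg p$ this rarely triggers.
- **Bootstrap quantiles** (both the balance cutoff $q$ and the interval
  endpoints) interpolate order statistics at the plotting positions
  $i/(B+1)$ (R's type 6). This is the exact inverse of the fractional rank
  pre-pivot, which also places the $i$-th order statistic at $i/(B+1)$;
  a centre-biased plotting position would systematically shorten the extreme
  tails at finite $B$ and cost real coverage. Ties take midranks.
- **Clipping**: $q$ cannot exceed $B/(B+1)$; reaching that ceiling means $B$
  cannot resolve the requested family-wise level (roughly, $B$ must exceed
  $2p/\alpha_S$), and the function warns. Default $B = 2000$ is adequate to
  $p$ of a few hundred at $\alpha_S = 0.05$ for single-ensemble intervals;
  comparison tables with $q_{\mathrm{total}} \approx 90$ need $B \gtrsim
  8000$.
- **Degenerate inputs**: constant columns are rejected by the correlation
  estimator (with a pointer to `filter_low_variance()`, default SD tolerance
  $10^{-9}$), yield zero-width intervals in the t-based methods, and
  resample to themselves in the bootstrap. Missing values are rejected, not
  imputed.
- **Determinism**: every stochastic function takes a `seed`; given one, the
  output is bit-reproducible. When called inside a larger seeded harness
  (e.g. `run_coverage_experiment()`), leaving `seed = NULL` lets one outer
  seed drive everything.

## Problem sizes used in validation

The test suite validates coverage at deliberately modest scales chosen to
give sharp Monte Carlo bands: Bonferroni on independent normals at
$p = 20, n = 500$ over 1000 replicate datasets (coverage must not fall more
than three Monte Carlo standard errors below nominal); ENCI on exchangeably
correlated normals ($\rho = 0.8$, $p = 10$, $n = 500$, 400 replicates,
$M = 2 \times 10^4$) within three MC standard errors of nominal; the
bootstrap on skewed copula data ($p = 5$, $n = 500$, 500 replicates,
$B = 1000$) within $\pm 0.03$ of nominal with per-variable left/right miss
rates agreeing within 0.02. The acceptance script re-runs the first two at
1000 replicates with $M = 10^5$. FCC ensembles are validated at $r = 10$,
5000 models.

## Limitations

- The family-wise guarantees are for means of finite-variance outputs;
  extremely heavy tails (infinite skewness) degrade all three methods.
- ENCI's correlation estimate needs $n$ comfortably above $p$; in the
  $p > n$ regime the equicoordinate quantile is computed on a repaired,
  rank-deficient correlation and should be treated as approximate.
- The bootstrap's balance guarantees are exact in the resampling world and
  first-order accurate in the real world; at small $n$ with strong skew a
  residual coverage error of order $1/\sqrt n$ per tail remains.
- The sample-size formula is Bonferroni-specific and conservative by
  construction; no power analysis for planted effect sizes is provided.
- No step-down multiple-testing procedures (Holm, Benjamini–Hochberg) are
  included: the workflow is single-step interval construction throughout.
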