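---
title: "Score-based structural change tests and their permutation null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based structural change tests and their permutation null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctperm)
```

## The model and the test

A structural change test (SCT) asks whether the k parameters of a fitted
model are the same across all subgroups induced by an auxiliary variable
v. The null hypothesis is full invariance: θ does not depend on v. The
score-based version works with the per-observation gradient of the
log-likelihood at the full-data MLE,

$$s(\hat\theta, y_i) = \left.\frac{\partial \log L(\theta; y_i)}
{\partial \theta}\right|_{\theta = \hat\theta},$$

which sums to zero over observations by the first-order condition of
maximum likelihood. Ordering the scores by v and cumulating gives the
fluctuation process $\Psi(t) = n^{-1/2}\sum_{i \le \lfloor nt\rfloor}
s(\hat\theta, y_i)$, decorrelated as $B(t) = \hat I^{-1/2}\Psi(t)$ with
$\hat I = n^{-1}\sum_i s_i s_i^{\top}$, the outer-product-of-gradients
(OPG) estimate of the score covariance. Under invariance $B(\cdot)$
converges weakly to k independent Brownian bridges; under a parameter
shift along v it develops a systematic excursion with a peak near the
change point.

Three aggregations of $B_{ij} = B(i/n; \hat\theta_j)$ are provided:

* DM $= \max_{i,j} |B_{ij}|$ — one process strays far, anywhere;
* CvM $= n^{-1}\sum_{i,j} B_{ij}^2$ — diffuse departures;
* maxLM $= \max_{i \in [i_{lo}, i_{hi}]}
  \left[\tfrac{i}{n}\left(1-\tfrac{i}{n}\right)\right]^{-1}
  \sum_j B_{ij}^2$ — all processes break at the same observation, the
  natural choice for a subgroup difference and the default here.

These are the standard score-based SCT forms from the fluctuation-test
literature; the maxLM weight is the variance of the bridge at t, so the
scan is a standardized single-break LM test maximized over break
candidates.

### Supported models and their scores

*Linear regression*: scores for coefficient j at observation i are
$x_{ij}(y_i - x_i^\top\hat\beta)/\hat\sigma^2$ with the ML variance
$\hat\sigma^2 = RSS/n$ profiled out. All mean coefficients (intercept
included, droppable via `test_intercept = FALSE`) form the tested set;
testing the nuisance variance is not of substantive interest and
excluding it matches common SCT practice.

*Saturated Gaussian graphical model*: the multivariate normal in mean /
precision parametrization. The tested set has $k = p(p+3)/2$ entries —
p means ("thresholds"), p precision diagonals, and $p(p-1)/2$
off-diagonal precision entries ("interactions"), each symmetric pair
being one free parameter whose derivative counts both occurrences. The
ML covariance uses the 1/n denominator deliberately: with it the score
identity $\sum_i s(\hat\theta, y_i) = 0$ holds exactly, which pins the
fluctuation process to zero at t = 1 and is the contract everything
downstream relies on.

The OPG estimate is used for $\hat I$ in both models (rather than an
analytic Hessian) because it is exactly the "covariance of the scores"
that the decorrelation step needs, and it treats both families
uniformly. The inverse square root is the symmetric eigendecomposition
root — basis-order invariant, unlike a Cholesky factor. A numerically
singular $\hat I$ (relative eigenvalue below 1e-10) is a hard error;
silently ridging it would invalidate the bridge approximation without
warning.

## Two null distributions

**Asymptotic**: simulate k-dimensional Brownian bridges on the same
grid (grid size = n, so the trim window maps one-to-one) and apply the
same statistic; the p value is the exceedance proportion among
`n_sim = 20000` draws (the default; raising it sharpens the p-value
resolution at linear cost). Closed forms exist for special cases — the
DM statistic with k = 1 follows the Kolmogorov distribution
$P(\sup|B^0| \le x) = 1 + 2\sum_j (-1)^j e^{-2j^2x^2}$, and the CvM
reference has mean k/6 — and the test suite uses them as independent
oracles for the simulated reference.

**Permutation**: under invariance, v carries no information about the
data, so the observation labels are exchangeable. The permutation null
recomputes the statistic under `n_perm` uniformly random rearrangements
of v. Because the full-data MLE, scores and $\hat I$ do not depend on
row order, nothing is refitted: the v-ordered, decorrelated score rows
are permuted, cumulated and re-aggregated — a compiled O(nk) loop per
rearrangement. The p value is $(1 + \#\{S^{perm} \ge S^{obs}\})/
(n_{perm}+1)$, the +1-corrected count that guarantees a valid level-α
test and a strictly positive p value; ties count toward the null
(conservative). The default `n_perm = 5000` balances p-value resolution
against cost; the simulation engine uses 1000 per replicate.

Why bother? The bridge approximation carries a Taylor remainder that
vanishes only at rate $1/\sqrt{n}$, and it degrades sharply as k grows.
At p = 15 nodes (k = 135) and n = 200 the asymptotic test rejects at
the 5% level well under 2% of the time and its null p values pile up
near 1, while the permutation p values remain uniform. The acceptance
suite measures both behaviors.

## Trimming

The maxLM weight $(t(1-t))^{-1}$ explodes at the endpoints, so the scan
excludes the tails: observations $[n_p, n - n_p]$ for the GGM (with
$n_p = p(p+3)/2$ free parameters) and the central 80% for the linear
model. For p = 15 at n = 200, $n_p = 135 > n/2$ leaves the stated GGM
window empty; the package then falls back to symmetric 10% fraction
trimming with a warning, the loosest conventional rule that keeps the
cell computable. Window endpoints are inclusive; the process is kept on
the full (n+1)-point grid including both pinned endpoints so the
boundary identities are directly testable.

Ties in v are broken by original row index (stable sort). Any strictly
increasing transform of v leaves the process, and hence every result,
unchanged.

## The synthetic-data generators

`generate_ggm_h0(p, n, edge_prob = 0.2)` draws a sparse conditional
dependence graph — each of the $\binom{p}{2}$ pairs is an edge with
probability 0.2 — with edge partial correlations uniform on
$\pm[0.1, 0.4]$, assembles the precision matrix with unit diagonal, and
rescales to unit partial variances. If the assembled matrix is not
safely positive definite (smallest eigenvalue below 0.05) a
diagonal-dominance repair is applied first, which guarantees positive
definiteness on every draw at the cost of shrinking the nominal partial
correlations in that (rare) case. The auxiliary v is uniform(0,1),
independent of the data, so invariance holds by construction.
`generate_linear_h0(q, n)` is pure noise: standard normal covariates,
zero coefficients, unit variance.

`generate_ggm_alternative` splits the sample at the median of v
(configurable quantile) and shifts the partial correlation of one
randomly chosen existing edge (configurable count; force-added when the
base graph is empty) by +Δθ for the upper subgroup, clipped at 0.95.
This is the simplest design in which "a parameter differs by Δθ between
subgroups" is literally true on a dimensionless scale, and it is the
package's fixed reading of an under-determined simulation protocol; the
resulting power is correspondingly that of a *single*-parameter shift
scanned by a k-parameter maxLM, which is modest at small Δθ. What these
generators do not emulate: non-Gaussian margins, dependent or discrete
auxiliary variables, drifts that are gradual in v rather than a single
break, and model misspecification beyond the subgroup shift — so
passing simulations certify calibration and relative power under clean
Gaussian two-group conditions, not robustness on messy real data.

## Numerical and design choices

* Scores, cumulation and all statistics are exact vectorized algebra;
  the only stochastic components are the two Monte Carlo nulls, both
  driven by R's RNG (compiled code uses `norm_rand`/`unif_rand`), so a
  single `set.seed`/`seed =` makes every result bit-reproducible.
* Degenerate inputs — constant columns, exact collinearity, zero
  residual variance, constant v, NA cells — are hard errors, never
  silently repaired.
* The simulated bridge lives on a discrete grid, so its supremum is
  biased slightly low relative to the continuous-time law (the match to
  the Kolmogorov CDF tightens like the grid's inverse square root);
  references are therefore built on the *observed* grid size, which
  makes the comparison finite-sample-consistent rather than
  asymptotically idealized.
* Study defaults are 500 replications with 1000 permutations — rates
  then carry binomial Monte Carlo error of about 0.01 at the 5% level —
  with full-scale runs available through the arguments.
* α = 0.05 for all reported rejection rates, the conventional level.

## Known limitations

Only the two built-in model families ship scores; penalized GGM fits,
non-Gaussian models, and recursive partitioning on top of the SCT are
out of scope. The permutation null, while exchangeability-exact under
H0, still pays its O(`n_perm` · n · k) price per test; the compiled
loop keeps a 135-parameter, n = 200 test with 5000 rearrangements well
under a second, but very large n·k will scale linearly beyond that.
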