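---
title: "Interval estimation for indirect effects: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation for indirect effects: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indirectci)
```

## The models

`indirectci` works with two saturated path models of observed variables.
The simple mediation model,

$$m = i_m + a x + e_m, \qquad y = i_y + b m + c' x + e_y,$$

and the serial model with two mediators, in which $x \to m_1 \to m_2 \to
y$ carries the indirect route ($a$, $b_1$, $b_2$), $c'$ is the direct
path, and the two remaining cross paths ($x \to m_2$, $m_1 \to y$) are
zero in every generating population but always estimated, so that the
fitted model is just identified and reproduces the sample moments
exactly.

The unstandardized indirect effect is the product of the mediated paths
($ab$, or $a b_1 b_2$). The completely standardized effect rescales it
to the z-score metric:

$$ab_{\text{std}} = ab\,\sqrt{\frac{\sigma_x^2}{\operatorname{Var}(y)}},
\qquad
\operatorname{Var}(y) = b^2\sigma_{e_m}^2 + \sigma_{e_y}^2 +
\sigma_x^2 (ab + c')^2$$

for the simple model, with the serial analogue obtained from the
reduced form. Two equivalent routes to the standardized effect —
the model-implied formula above and `standardize_by_sds(ab, sd_x, sd_y)`
— coincide whenever `sd_y` is the implied outcome SD; the test suite
asserts this identity.

**Serial standardizer.** For the serial model we compute the implied
$\operatorname{Var}(y)$ from the *full* parameter set, including the
estimated zero-population cross paths, rather than from the
mediated-chain terms only. At the optimum the two coincide (the
saturated model reproduces the sample variance of $y$); away from the
optimum — which is where the profile search lives — only the full form
is internally consistent with the likelihood being profiled. This was a
genuinely open choice and this is the package's resolution of it.

## The five interval procedures

* **Percentile bootstrap** (`boot`): resample the $n$ cases with
  replacement $B = 2000$ times (default), re-estimate the effect by OLS
  in each resample — with the standardizers recomputed *within* each
  resample — and take the 2.5th/97.5th empirical percentiles. We use the
  linear-interpolation quantile definition (R's type 7); no specific
  order-statistic rule is canonical here, and at $B = 2000$ the choice
  moves the limits by a negligible amount.
* **Profile likelihood-based intervals** (`lbci`, `lbci-adf`,
  `lbci-fx`): invert the 1-df chi-square test at level $\alpha$: the
  interval is the range of $g(\theta)$ subject to
  $D(\theta) - D(\hat\theta) \le \chi^2_1(1-\alpha) = 3.8415$, where $D$
  is the −2 log-likelihood (ML engines) or the scaled ADF statistic
  $(n-1)F$. The critical value is computed by `qchisq()`, not a rounded
  constant.
* **Monte Carlo** (`mc`): draw 1000 sets (default) of independent
  normal values per path, centered at the OLS estimates with SDs equal
  to their standard errors, and take percentiles of the products. The
  cross-path covariance is fixed at zero — the sampling covariance of
  $\hat a$ and $\hat b$ is zero in these models — and the serial model
  uses three independent normals. The standardized variant multiplies
  both limits by $s_x / s_y$, treating the standardizers as fixed; this
  is exactly the procedure whose fragility for medium and large
  standardized effects the simulations expose.

## Estimation engines

All three engines operate on sample moments (`compute_moments()`), never
on raw data, and all three reproduce the OLS point estimates for these
just-identified models — an equivalence the tests assert to 1e-6.

* **ML**: the multivariate-normal −2 log-likelihood with the ML (divisor
  $n$) covariance. The likelihood of a recursive path model factors into
  one block per regression ($x$; $m\mid x$; $y\mid m,x$; and the serial
  analogues), which gives a separable deviance with analytic gradients;
  a matrix-form `minus_two_loglik()` is kept as the reference and the
  two are asserted equal at random parameter values. Mean parameters are
  always profiled out at their saturated optimum. We profile the
  $N$-consistent −2lnL directly; an $N-1$ rescaling would change the
  limits by $O(1/n)$ and neither convention is privileged for a
  saturated model.
* **ADF/WLS**: minimizes $(s - \sigma(\theta))^\top W^{-1} (s -
  \sigma(\theta))$ over the half-vectorized covariance structure with
  $W_{(ij),(kl)} = m_{4}[ijkl] - s_{ij}s_{kl}$ built from biased
  (divisor $n$) central fourth moments. Means are fitted saturated and
  excluded from $W$: the indirect effects are functions of the
  covariance structure only. The statistic profiled is $(n-1)F$;
  $nF$ is a config-level alternative that changes nothing
  qualitatively. Under normality $W_{(ij),(kl)} \to s_{ik}s_{jl} +
  s_{il}s_{jk}$, which the tests use as a sanity oracle.
* **Fixed-X ML**: identical to ML with $\sigma_x^2$ held at the
  divisor-$n$ sample variance and removed from the free parameters,
  matching the ML framework's internal convention. For a saturated model
  this changes no other estimate — asserted in the tests — but it does
  change the profile of the *standardized* effect, because the
  standardizer's sampling variability is no longer propagated.

## The profile search

The generic bound search computes the profiled discrepancy $P(c) =
\min\{D(\theta) : g(\theta) = c\}$ by an augmented-Lagrangian inner
minimization (BFGS on $D + \lambda(g-c) + \rho(g-c)^2$, warm-started
across candidate values of $c$), expands a bracket away from
$\hat g$ until $P$ exceeds $D(\hat\theta) + 3.8415$, and root-finds the
crossing. Endpoints therefore satisfy the constraint with equality to
fine tolerance; a side that cannot be bracketed or whose inner solves
keep failing after five deterministic restarts (steps of about one
delta-method SE along the gradient of $g$) is flagged
`failed-lower`/`failed-upper` and reports the best feasible value rather
than being silently dropped. A locally constant $g$ short-circuits to a
point interval. Variances enter the free vector on the log scale, so
every visited $\theta$ is feasible and no positivity constraints are
needed.

For the unstandardized effect in the simple model under the ML engines,
the block factorization collapses the profile to two one-dimensional
quadratics: $D(a, b) = n\log(v_m(a)/v_m(\hat a)) +
n\log(v_y(b)/v_y(\hat b))$ with closed-form solutions for the admissible
$b$ at each $a$. The package uses this closed path inside simulation
loops and checks it against the generic search (and against a
brute-force constrained-extremum oracle on a dense $(a, b)$ grid) in the
tests.

## The data generator

`generate_dataset()` emulates the simulation-study populations exactly:

* the predictor is drawn from one of five families — normal,
  exponential(rate 1), beta(1.5, 1.5), t(5), t(6) — and shifted/scaled
  by the family's *population* constants so its population mean and SD
  are 0 and 1 (e.g. beta: mean 0.5, SD 0.25; t(5): SD $\sqrt{5/3}$);
* each downstream variable is its structural equation plus a normal
  error whose variance keeps every variable at unit population variance:
  $\sigma_{e_m}^2 = 1 - a^2$ and $\sigma_{e_y}^2 = 1 - b^2 - c'^2 -
  2abc'$ for the simple model, and — derived here from the same
  unit-variance constraints, then verified against a million-case
  simulated variance oracle — $\sigma_{e_{m_2}}^2 = 1 - b$ and
  $\sigma_{e_y}^2 = 1 - b - c'^2 - 2abc'$ for the serial model with
  $b_1 = b_2 = \sqrt b$;
* the variables are then affinely rescaled to means (3, 5, 4) and SDs
  (4, 5, 3) for $x, m, y$ (serial: $m_1 \to (5, 5)$, $m_2 \to (2, 2)$),
  so unstandardized and standardized coefficients differ — a guard
  against conflating the two scales. The dataset carries the true
  rescaled effects as attributes: standardized $ab$ unchanged,
  unstandardized $ab \cdot \text{SD}_y/\text{SD}_x$.

The direct path is parameterized by the population $R^2$ increase $d$
from adding $x$ to the outcome regression. On the standardized scale
that increase is the squared semipartial correlation $c'^2(1 - a^2)$,
so the generator inverts it as $c' = \sqrt{d/(1-a^2)}$, taking the
positive root (the design is sign-symmetric). Grid cells whose implied
outcome $R^2$ exceeds 0.80, or whose implied error variance would be
negative, are dropped.

Seeding: each replication receives one seed, from which the predictor
and every error vector take independent sub-seeds; interval procedures
are seeded separately by the runner, so resampling never shares a
stream with data generation, and results are identical regardless of
scheduling order.

What the generator does *not* emulate: nonnormal **errors** (the
deliberate contrast case — here the OLS/ML distributional assumptions
for the paths are intentionally satisfied), measurement error, latent
variables, or additional covariates. Passing coverage tests on these
populations therefore says nothing about robustness to misspecified
error distributions.

## The coverage study

`run_condition()` replicates a condition, forms every requested interval
for both effect scales, and tests closed-interval containment of the
true rescaled effects. Failed bound searches are excluded from that
method's denominator and counted (`n_converged`), which mirrors common
practice; a coverage estimate is then the proportion of converged
replications whose interval contains the truth. Estimated coverage is
classified against the closed tolerable range [0.935, 0.965] around the
nominal 0.95. The number of replications is a configuration value with
default 1000; this is an explicit choice of this package, not an
inference about any external study.

## Problem sizes used by the tests and the acceptance script

Unit tests use large-sample checks at $10^5$–$10^6$ draws for moment
oracles, and reduced replication counts (150–600) for stochastic
coverage properties; the headline coverage checks run 2000 replications
at $n = 500$ (bootstrap, 1000 resamples) and $n = 100$ (ML profile).
These sizes were chosen so the binomial noise of a coverage estimate
(SE $\approx$ 0.005 at 2000 replications) is small against the width of
the tolerable range while a full run stays in the minutes range on one
core. The full factorial design (2 models × 5 n × 8 path pairs × 4
direct effects × 5 distributions, minus dropped cells) is exposed via
`build_condition_grid()` but is a multi-hour computation at
publication-scale replication counts; the package reproduces the
design's *qualitative* contrasts (e.g. ML profile under-coverage for
heavy-tailed predictors at medium standardized effects, with the ADF
engine and the bootstrap staying near nominal) as stochastic tests at
reduced scale.

## Numerical choices and known limitations

* Covariance divisor: $n$ (ML convention) throughout the likelihood and
  the ADF weight matrix; the unbiased matrix is also exposed by
  `compute_moments()`.
* Optimizers start at the OLS-derived values, which are exact for these
  saturated models, so "convergence" failures essentially only arise in
  the constrained profile solves, where they are flagged per side.
* The ADF weight matrix needs $n$ comfortably above the number of
  distinct covariance elements (6 for the simple, 10 for the serial
  model); at $n = 50$ with four variables it is near-singular often
  enough that profile failures are visibly more common — consistent
  with ADF's known large-sample requirements.
* Bootstrap resamples with a rank-deficient design are redrawn and
  counted; more than 5% redraws raises a warning. With continuous data
  this is essentially never triggered.
* The Monte Carlo method is implemented exactly as specified — fixed
  standardizers, zero cross-path covariance — including its known
  failure mode for standardized effects; it is a comparison target, not
  a recommendation.
* Heavy-tailed moment diagnostics converge slowly: the sample kurtosis
  of t(5)/t(6) draws has infinite sampling variance, so simulated
  checks of those constants use wide bands by design.
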