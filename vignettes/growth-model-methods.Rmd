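---
title: "Methods: Bayesian cohort-sequential growth models of cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian cohort-sequential growth models of cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the modeling strategy

Education is robustly associated with the *level* of cognitive performance
in adulthood. Whether it also changes the *rate* of age-related decline is
a different question, and the hypothesis that it does not — education
raises the curve without bending it, often called *passive reserve* —
coincides with a statistical null hypothesis. Classical significance
testing cannot accumulate evidence *for* such a null; Bayes factors can.

`cogdecline` implements the full chain needed to pose this question to
cohort-sequential longitudinal data and to verify every link of that chain
against known ground truth:

1. a synthetic cohort generator with the accelerated-longitudinal
   structure of a two-sample, five-wave aging study,
2. deterministic data preparation (exclusions, education derivation,
   T-standardization, centering, orthogonal age basis, design matrices),
3. a hierarchical growth model fitted by MCMC on the marginalized
   likelihood, and
4. Savage-Dickey density-ratio Bayes factors for the education-by-slope
   parameter under a graded family of priors.

## The model

For person $i$ at age $t$ the outcome (a T-standardized cognitive score)
follows

$$Y_{ti} = \beta_{0i} + \beta_{1i}\,\mathrm{age}_{ti}
          + \beta_{2i}\,\mathrm{age}^2_{ti} + \varepsilon_{ti},
  \qquad \varepsilon_{ti} \sim \mathrm{N}(0, \sigma_\varepsilon^2),$$

where $\mathrm{age}$ is centered and $\mathrm{age}^2$ is the quadratic
term orthogonalized against the constant and linear terms over all
retained person-period rows. The person-level coefficients are

$$\begin{aligned}
\beta_{0i} &= \gamma_{00} + \gamma_{01}c_i + \gamma_{02}e_i + \gamma_{03}s_i
            + \gamma_{04}m_i + \gamma_{05}c_ie_i + \gamma_{06}c_is_i
            + \gamma_{07}e_is_i + \gamma_{08}c_ie_is_i + u_{0i},\\
\beta_{1i} &= \gamma_{10} + \gamma_{11}c_i + \gamma_{12}e_i + \gamma_{13}s_i
            + \gamma_{14}c_ie_i + \gamma_{15}c_is_i + \gamma_{16}e_is_i
            + \gamma_{17}c_ie_is_i + u_{1i},\\
\beta_{2i} &= \gamma_{20} + \gamma_{21}c_i + \gamma_{22}e_i + \gamma_{23}s_i
            + \gamma_{24}c_ie_i + \gamma_{25}c_is_i + \gamma_{26}e_is_i
            + \gamma_{27}c_ie_is_i,
\end{aligned}$$

with $c_i$ the centered birth year (cohort, linear coding), $e_i$ centered
education in years, $s_i$ sex (0 male, 1 female), and $m_i$ the sample
code (0/1) entering the intercept only — two persons of the same age and
cohort in different samples differ only in testing experience, so sample
is a main-effect proxy for retest effects. The quadratic slope carries no
random term;
$(u_{0i}, u_{1i})$ is bivariate Normal with SDs $\sigma_{u0}$,
$\sigma_{u1}$ and correlation $\rho$. That yields 25 fixed effects
(`design_colnames()`) and four variance-structure parameters.

The focal parameter is $\gamma_{12}$ (`LS x Education`): the change in the
annual rate of decline (T-units/year) per additional year of education.
Under passive reserve, $\gamma_{12} = 0$.

**Identification.** Age, cohort and period are linearly dependent; the
model assumes no period effects, which is what lets age and cohort enter
jointly in a cohort-sequential design.

## Priors

Weakly informative priors are used for everything not under test:
Normal(50, 20) on the intercept (T-score scale), Normal(0, 3) on every
other coefficient, half-Cauchy(0, 10) on the three scale parameters, and
the flat LKJ(1) prior (uniform on $[-1, 1]$) on $\rho$. The residual-SD
prior is taken to be the same half-Cauchy(0, 10) as the other scales; we
treat that as a modeling choice of this package rather than settled
convention, since reasonable alternatives (e.g. a wider or
data-scaled half-Cauchy) would behave equivalently at these sample sizes.

The focal prior is $\gamma_{12} \sim \mathrm{N}(0, \sigma)$ with $\sigma$
equal to 1, 2 or 4 times the absolute value of a literature-based effect
estimate: 0.002 (visuospatial ability), 0.004 (semantic knowledge), 0.017
(episodic memory), in T-units per year of age per year of education. The
grid doubles as the prior-sensitivity analysis. Centering the alternative
on zero makes the test conservative: the alternative concentrates on
small effects, which is the hardest family to distinguish from the null.

## Likelihood and sampler

The person random effects are integrated out analytically: with
$Z_i = (\mathbf 1, \mathrm{age}_i)$ and
$\Sigma_u = \begin{pmatrix}\sigma_{u0}^2 & \rho\sigma_{u0}\sigma_{u1}\\
\rho\sigma_{u0}\sigma_{u1} & \sigma_{u1}^2\end{pmatrix}$,
person $i$'s observed rows are jointly Normal with mean $X_i\gamma$ and
covariance $Z_i \Sigma_u Z_i^\top + \sigma_\varepsilon^2 I$. Only
observed rows enter (no listwise deletion, no imputation); dropout is
treated as ignorable. Marginalization removes roughly two latent
dimensions per person from the sampling problem and leaves the posterior
over $(\gamma, \sigma_{u0}, \sigma_{u1}, \rho, \sigma_\varepsilon)$
unchanged. Internally the per-person contributions reduce, via the
Woodbury identity, to closed-form functions of 2×2 blocks built from
per-person sufficient statistics, so a likelihood evaluation is a handful
of vectorized operations regardless of the number of persons; the
exported `log_likelihood()` uses an independent per-person Cholesky route,
and the two are cross-checked against each other and against adaptive
Gauss–Hermite quadrature in the test suite.

Sampling exploits the structure of this marginal posterior:

* **Fixed effects**: given the variance parameters, the marginalized
  likelihood is Gaussian in $\gamma$ and the priors are Normal, so
  $\gamma$ is drawn exactly from its 25-dimensional Gaussian full
  conditional (one Cholesky solve per iteration).
* **Variance parameters**: $(\log\sigma_{u0}, \log\sigma_{u1},
  \operatorname{atanh}\rho, \log\sigma_\varepsilon)$ are updated by
  univariate slice sampling (stepping-out and shrinkage) with the
  appropriate Jacobian terms. Slice widths are tuned during warmup from
  the chain's running spread and frozen afterwards; two sweeps per
  iteration. Slice sampling was chosen over random-walk Metropolis after
  the latter mixed poorly on the weakly identified slope SD and
  correlation (a mild funnel when $\sigma_{u1}$ approaches zero).

Defaults mirror the conventional protocol: 4 chains, 2,000 post-warmup
draws each with an equal warmup (we read "2,000 samples" as post-warmup
draws; the alternative reading would halve the retained sample without
changing any conclusion), overdispersed variance-parameter starts, and
per-chain seeds derived deterministically from one master seed.
Convergence is monitored by the split-chain potential scale reduction
factor (`rhat()`, with a guard returning exactly 1 for zero-variance
degenerate chains); any parameter at or above 1.01 flags the fit as
non-converged (a warning on `fit_growth()`, an error at the end of
`run_analysis()`).

## Posterior summaries and the Bayes factor

* **MAP** is the maximizer of a Gaussian-kernel density estimate
  (Silverman's rule-of-thumb bandwidth, 512-point grid spanning the draw
  range) of each pooled marginal.
* **HDI** is the shortest contiguous interval containing 95% of the
  pooled sorted draws.
* **Savage-Dickey**: for the point null $\gamma_{12}=0$ nested in
  $\gamma_{12}\sim\mathrm N(0,\sigma)$,
  $\mathrm{BF}_{01} = p(\gamma_{12}=0 \mid y) / p(\gamma_{12}=0)$,
  *provided the posterior was sampled under that same prior*. The package
  therefore refits the model once per grid $\sigma$
  (`run_sensitivity()`), and `savage_dickey_bf()` refuses a fit whose
  recorded focal prior does not match. Chains are pooled before density
  estimation. The posterior density at zero is estimated two ways: a
  Gaussian KDE with Silverman bandwidth evaluated exactly at zero (the
  headline value) and a Normal approximation
  $\mathrm N(\bar\theta, s_\theta)$ at zero (always reported alongside; a
  discrepancy beyond 25% triggers a warning). The KDE is accurate when
  zero lies near the bulk of the posterior — the regime of the null
  analyses this test is built for; when zero sits far in the tail the
  Normal approximation is the more efficient estimator and the KDE's
  smoothing bias and tail Monte Carlo noise dominate, which is why both
  are carried. The reference fit under the weakly informative
  Normal(0, 3) focal prior is reported without a Bayes factor.

The exploratory cohort-by-education parameter ($\gamma_{05}$) is
summarized by interval estimation only (`exploratory_gamma05_report()`);
a 95% HDI with an endpoint exactly at zero counts as including zero.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the design skeleton of a two-sample
cohort-sequential aging study: five-year birth-cohort bands (defaults
1909–1959), five waves at five-year spacing (1989–2009), one sample
entering at wave 1 and a second at wave 2, ~100 persons per
cohort-by-sample cell, 54% women, education drawn once per person from
Normal(10.2, 3) rounded to whole years and truncated, permanent dropout
after any attended wave with a constant hazard (0.1 by default), and
outcomes generated from the exact Level-1/Level-2 equations above. The
default true parameters are literature-based estimates for the three
outcomes, including their variance components
(`default_truth()`). Specific choices:

* **Quadratic-block truths are read as per-decade².** Published
  acceleration estimates of order −0.1 to −0.15 are only physically
  plausible for T-scaled scores if the quadratic basis is scaled
  (quadratic normalization is exactly the convention such tables tend to
  leave unstated); applied to this package's raw squared-year basis they
  would imply tens of T-units of curvature at the age extremes. The
  defaults therefore divide the quadratic block by 100 (decade² →
  year²), giving sub-T-unit curvature over the observed span and a
  first-occasion outcome SD near 10 raw units.
* **Age** is the integer `test_year - birth_year`; an optional ±2-year
  uniform person-level jitter exists behind a flag (default off) so that
  fixtures stay exact.
* **Education SD = 3 years** is a placeholder for an unreported quantity;
  the population mean (10.2) is the only anchored value. Rounding to
  integer years adds the expected discrete-uniform variance, which the
  marginal tests allow for.
* **Dropout is MCAR** — independent of outcome level — matching the
  ignorable-missingness assumption of the likelihood. Outcome-dependent
  attrition, practice effects beyond the sample main effect, measurement
  floor/ceiling, and cohort-varying education distributions are *not*
  emulated; passing tests therefore certify the estimation machinery, not
  robustness to those real-data complications.
* **Exact round trip**: the generator evaluates the linear predictor on
  the centered covariates and the orthogonal quadratic basis computed
  from its own final (post-dropout) rows, using the same centering
  constants as the preparation defaults. Preparing generated data with
  matching constants and no exclusions reproduces the generating design
  matrix exactly, which is what makes noise-free round-trip tests and
  exact parameter-recovery comparisons possible. When preparation
  re-standardizes or excludes persons, the basis shifts slightly and
  recovery is only approximate — synthetic validation therefore uses
  `standardize = FALSE` (the generator already produces T-scale scores)
  with no exclusions triggered.

## Data preparation conventions

* **Education** is the maximum over per-wave reports; persons with no
  report at any wave, reports above 25 years, or below 6 years (a proxy
  for less-than-compulsory schooling, configurable) are removed, as are
  the earliest (1908–1910) and latest (1958–1960) cohort bands. Rules
  fire in that order and each person is counted once.
* **T-standardization** anchors to the *first measurement occasion*
  (smallest wave present): $T = 50 + 10(y - m)/s$ with $m, s$ the
  first-occasion mean and *population* SD (divide by $n$). The population
  convention is arbitrary but fixed and documented so that exactness
  tests are well defined; at $n \ge 100$ the difference from the sample
  convention is negligible.
* **Centers**: age 62.9 years, cohort 1933, education 10.2 years by
  default; `recompute_centers_from_data` recenters at the retained rows'
  means for synthetic designs with different support.
* **Orthogonal quadratic age**: the residual of $\mathrm{age}^2$ after
  least-squares projection onto $\{1, \mathrm{age}\}$, pooled over all
  retained person-period rows (one basis, one design matrix — not per
  person or per wave), in raw residual units (not rescaled to unit norm).
  The raw-residual convention keeps $\gamma_{20}$ in T-units per
  squared-year-like units; recovered quadratic-block coefficients are
  comparable only under the same convention. A second Gram–Schmidt
  refinement pass removes the $O(\varepsilon\,\lVert q\rVert)$ residual
  the first projection leaves on long rowsets, keeping
  $\sum q$ and $\sum q\,\ell$ below $10^{-8}$ absolute even at full
  study scale.
* **Sample coding**: the lexicographically later label gets 1 (S1 → 0,
  S3 → 1) — an arbitrary, fixed reference.

## Numerical and testing choices

Degenerate inputs are handled explicitly: zero random-effect SDs reduce
the likelihood to iid Normal form; a zero-row dataset makes the posterior
equal the prior (used as a sampler-correctness test via
Kolmogorov–Smirnov against the prior marginals); constant draws give
R̂ = 1 and a degenerate `[c, c]` HDI; out-of-support parameter values
yield a log prior of $-\infty$, not an exception.

Validation problem sizes were chosen to keep the full suite at desk
scale while remaining informative: oracle checks run on a 3-person
fixture against adaptive Gauss–Hermite quadrature (agreement to
$10^{-6}$); recovery, convergence, Bayes-factor direction and power
checks run on 400-person synthetic cohorts (8 cohorts × 2 samples × 25
per cell, dropout 0.1), with the full 4 × 2,000 protocol for the
reference fit and 20 lighter replicate fits for HDI-coverage scoring.
The semantic-knowledge truth set anchors the recovery and convergence
studies because its random-slope SD (0.143) is the best identified of
the three outcomes; the episodic-memory prior grid (0.017/0.034/0.068)
anchors the Bayes-factor studies, where the graded-width pattern is most
visible. At 400 persons the focal parameter's likelihood SD (~0.013) is
comparable to the tightest episodic-memory prior width, so strict
per-replicate monotonicity of BF$_{01}$ in $\sigma$ — which holds when
the posterior at zero is data-dominated — is asserted up to three
propagated Monte Carlo standard errors of the density estimates; at the
original study's ~1,700 persons the premise, and hence strict
monotonicity, is comfortably satisfied.

## Limitations

* The no-period-effects assumption is an identification device, not a
  finding; the generator builds data that satisfy it.
* MCAR dropout in the generator is kinder than reality; the model's
  ignorability assumption is exercised, not stressed (an
  outcome-dependent hazard hook exists for robustness studies).
* Savage-Dickey density estimation at zero degrades when the posterior
  mass sits far from zero; BF$_{10}$ values in that regime are reliably
  "large" but not precise, and the Normal-approximation diagnostic should
  be consulted.
* The correlation $\rho$ is weakly identified whenever $\sigma_{u1}$ is
  small (true for all three outcome truth sets); its posterior is then
  prior-influenced and wide. This mirrors the estimand's geometry, not a
  sampler defect — the slice sampler traverses the region with split-R̂
  comfortably below 1.01.
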