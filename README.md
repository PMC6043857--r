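# cogdecline

Does education change the *rate* of age-related cognitive decline, or
only the *level* of cognitive performance? The hypothesis that it leaves
the rate untouched — "passive reserve" — coincides with a statistical
null, and evidence *for* a null needs Bayesian machinery. `cogdecline`
is an R package plus an analysis workflow for posing that question to
cohort-sequential (accelerated longitudinal) data: a hierarchical
growth model fitted by MCMC on the random-effects-marginalized
likelihood, Savage-Dickey density-ratio Bayes factors for the
education-by-slope parameter under a graded prior-sensitivity grid, and
a synthetic cohort generator that emulates a two-sample, five-wave
aging study so that every stage is testable against known ground truth.
It is written for quantitative researchers in cognitive aging and
longitudinal methodology.

## The model

For person *i* at (centered) age *t*, a T-standardized cognitive score
follows

    Y_ti = b0_i + b1_i * age_ti + b2_i * age2_ti + e_ti,   e_ti ~ N(0, s_e^2)

where `age2` is the quadratic age term orthogonalized against `{1, age}`
over all retained rows. Intercepts and linear slopes carry person-level
random effects `(u0_i, u1_i) ~ N2(0, S_u)` (SDs `s_u0`, `s_u1`,
correlation `rho`) and are modeled by cohort (linear birth-year coding),
education (years, centered), sex, sample (intercept only) and their
interactions — 25 fixed effects in all. The focal parameter is
`gamma_12` (`LS x Education`): the change in annual decline rate
(T-units/year) per year of education.

Priors: Normal(50, 20) intercept, Normal(0, 3) coefficients,
half-Cauchy(0, 10) scales, flat LKJ(1) correlation. The focal prior is
Normal(0, sigma) with sigma = {1, 2, 4} x |literature estimate| (0.002
VA / 0.004 SK / 0.017 EM T-units per year per year); for each sigma the
model is refitted and

    BF01 = p(gamma_12 = 0 | data) / p(gamma_12 = 0)

is the posterior/prior density ratio at zero (Savage-Dickey). Sampling
is blocked: exact Gaussian conditional draws for the coefficients,
slice sampling for the variance parameters, split-chain Rhat < 1.01 as
the convergence protocol.

## Worked example

Simulate a small two-sample cohort study with a known null
education-by-slope effect, fit it, and test the null:

```r
library(cogdecline)

design <- study_design(cohort_birth_years = seq(1919, 1954, by = 5),
                       persons_per_cell = 25, dropout_hazard = 0.1,
                       education_min = 6, education_max = 25)
truth <- default_truth("em")                   # episodic-memory truth set
truth$gamma["LS x Education"] <- 0             # impose the null

dat  <- generate_cohort(design, list(em = truth), seed = 42)
prep <- prepare_dataset(dat, "em",
                        prep_config(standardize = FALSE,
                                    excluded_cohorts = list(),
                                    education_min_allowed = 0))
fit  <- fit_growth(prep, prior_spec(), chains = 4, iter = 2000, seed = 1)
summarize_fit(fit)[c(1, 10, 12, 18), ]

sens <- run_sensitivity(prep, sensitivity_grid(-0.017),
                        chains = 4, iter = 1000, seed = 2)
sens$table
```

The summary rows print MAP, posterior mean, 95% HDI and split-chain
Rhat for the intercept, linear slope, focal `LS x Education` and
quadratic slope:

```
      parameter      map     mean hdi_lower hdi_upper rhat
      Intercept 47.81590 47.64473   45.5564  49.82747    1
             LS -0.06505 -0.07180   -0.1932   0.04892    1
 LS x Education -0.01256 -0.01332   -0.0559   0.03096    1
             QS -0.00585 -0.00572   -0.0137   0.00223    1
```

The focal HDI covers zero and all Rhat < 1.01. The sensitivity table
gives one row per prior width plus the Normal(0, 3) reference row:

```
 outcome prior_sigma      map hdi_low hdi_high bf01  bf10
      em       0.017 -0.00701 -0.0310   0.0217 1.17 0.854
      em       0.034 -0.01313 -0.0462   0.0258 1.64 0.610
      em       0.068 -0.01145 -0.0530   0.0274 2.79 0.358
      em       3.000 -0.01196 -0.0554   0.0320   NA    NA
```

BF01 > 1 throughout and growing with the prior width: on null data, the
wider the alternative, the more the Savage-Dickey ratio rewards the
null, while the focal MAP itself barely moves. The same qualitative
pattern at the full simulated scale (stage 04 below, ~1,700 retained
persons) gives BF01 = 1.66 / 2.79 / 5.42 for episodic memory.

## The analysis workflow

Numbered drivers under `analysis/` run the full emulated study
(2,200 simulated persons, three outcomes) stage by stage, writing
tables under `results/`:

| script | what it does | output |
|---|---|---|
| `01_simulate.R` | synthetic cohort (11 cohorts x 2 samples x 100) | `synthetic_cohort.csv` |
| `02_prepare.R` | exclusions, T-scores, design matrices | `prepared_*.csv`, `design_*.csv` |
| `03_fit_growth_model.R` | reference fits, 4 chains | `table1_*.csv`, `draws_*.csv` |
| `04_bayes_factors.R` | Savage-Dickey sensitivity grid | `table2_*.csv` |
| `05_trajectories.R` | model-implied trajectories, slope contrasts | `trajectories_*.csv`, `slope_contrasts.csv` |

`run_analysis()` performs the same pipeline in one call from a
`run_config()` or YAML file.

## Layout

- `R/` — generator, preparation, likelihood/sampler, Bayes factors,
  pipeline
- `analysis/` — the numbered workflow drivers
- `tests/testthat/` — unit, property and acceptance suites (oracles
  built in code)
- `vignettes/growth-model-methods.Rmd` — the model, its assumptions,
  numerical conventions and limitations
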