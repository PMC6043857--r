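#' Fixed-effect design column names
#'
#' The model has 25 fixed effects in three blocks: an intercept block
#' (intercept, cohort, education, sex, sample and the cohort/education/sex
#' interactions), a linear-slope block (`LS`, the linear age basis crossed
#' with the same covariates except sample), and a quadratic-slope block
#' (`QS`, the orthogonalized quadratic age basis crossed likewise).  Sample
#' enters as a main effect only, to absorb retest experience.
#'
#' @return character vector of length 25.
#' @export
design_colnames <- function() {
  covs <- c("Cohort", "Education", "Sex",
            "Cohort x Education", "Cohort x Sex", "Education x Sex",
            "Cohort x Education x Sex")
  c("Intercept", "Cohort", "Education", "Sex", "Sample",
    "Cohort x Education", "Cohort x Sex", "Education x Sex",
    "Cohort x Education x Sex",
    "LS", paste("LS x", covs),
    "QS", paste("QS x", covs))
}

#' Full model parameter names
#'
#' The 25 fixed effects of [design_colnames()] followed by the four
#' variance-structure parameters: between-person intercept SD (`sd_u0`),
#' between-person linear-slope SD (`sd_u1`), their correlation (`rho`) and
#' the residual SD (`sd_resid`).
#'
#' @return character vector of length 29.
#' @export
param_names <- function() {
  c(design_colnames(), "sd_u0", "sd_u1", "rho", "sd_resid")
}

# Index of the focal education-by-linear-slope coefficient in the design.
focal_index <- function() match("LS x Education", design_colnames())

#' Cohort-sequential study design
#'
#' Describes a two-sample accelerated longitudinal design: five-year birth
#' cohorts, a fixed grid of testing waves at constant spacing, each sample
#' entering at its own wave, with monotone per-wave dropout.  The defaults
#' emulate a design with eleven cohorts (band midpoints 1909--1959), waves
#' in 1989--2009 at five-year spacing, a first sample entering at wave 1
#' and a second at wave 2, roughly one hundred persons per cohort-by-sample
#' cell, 54% women and self-reported education averaging 10.2 years.
#'
#' @param cohort_birth_years midpoints (calendar years) of the five-year
#'   birth-cohort bands.
#' @param persons_per_cell number of persons per cohort-by-sample cell.
#' @param sample_entry_waves named integer vector mapping sample label to
#'   the first wave attended.
#' @param wave_years calendar years of the testing waves (strictly
#'   increasing, constant spacing).
#' @param wave_spacing years between waves; must match `diff(wave_years)`.
#' @param dropout_hazard per-wave probability of permanent dropout after an
#'   attended wave, in `[0, 1]`.
#' @param female_fraction probability that a person is female, in `[0, 1]`.
#' @param education_mean,education_sd mean and SD (years) of the Normal from
#'   which person-level education is drawn (rounded to whole years).
#' @param education_min,education_max truncation bounds (years) applied to
#'   drawn education.
#' @return object of class `study_design`.
#' @seealso [generate_cohort()]
#' @export
study_design <- function(cohort_birth_years = seq(1909, 1959, by = 5),
                         persons_per_cell = 100L,
                         sample_entry_waves = c(S1 = 1L, S3 = 2L),
                         wave_years = seq(1989, 2009, by = 5),
                         wave_spacing = 5,
                         dropout_hazard = 0.1,
                         female_fraction = 0.54,
                         education_mean = 10.2,
                         education_sd = 3,
                         education_min = 0,
                         education_max = 25) {
  if (length(cohort_birth_years) < 1L || anyNA(cohort_birth_years))
    stopf("'cohort_birth_years' must be a non-empty numeric vector")
  if (!is.numeric(persons_per_cell) || length(persons_per_cell) != 1L ||
      is.na(persons_per_cell) || persons_per_cell < 1)
    stopf("'persons_per_cell' must be a positive count")
  if (length(wave_years) < 2L) stopf("need at least two waves")
  sp <- diff(wave_years)
  if (any(sp <= 0) || any(abs(sp - sp[1L]) > 1e-8))
    stopf("'wave_years' must be strictly increasing with constant spacing")
  if (abs(sp[1L] - wave_spacing) > 1e-8)
    stopf("'wave_spacing' (%s) does not match diff(wave_years) (%s)",
          wave_spacing, sp[1L])
  if (is.null(names(sample_entry_waves)) || any(names(sample_entry_waves) == ""))
    stopf("'sample_entry_waves' must be a named vector of wave indices")
  if (any(sample_entry_waves < 1L) ||
      any(sample_entry_waves > length(wave_years)))
    stopf("'sample_entry_waves' values must be valid wave indices")
  if (length(sample_entry_waves) > 2L)
    stopf("at most two samples are supported (sample enters the model as a single 0/1 code)")
  assert_probability(dropout_hazard, "dropout_hazard")
  assert_probability(female_fraction, "female_fraction")
  if (!(education_min <= education_mean && education_mean <= education_max))
    stopf("need education_min <= education_mean <= education_max")
  structure(list(
    cohort_birth_years = as.numeric(cohort_birth_years),
    persons_per_cell = as.integer(persons_per_cell),
    sample_entry_waves = sample_entry_waves,
    wave_years = as.numeric(wave_years),
    wave_spacing = as.numeric(wave_spacing),
    dropout_hazard = dropout_hazard,
    female_fraction = female_fraction,
    education_mean = education_mean,
    education_sd = education_sd,
    education_min = education_min,
    education_max = education_max
  ), class = "study_design")
}

#' Ground-truth parameters for the synthetic generator
#'
#' Holds the 25 fixed effects (named as in [design_colnames()]), the
#' between-person intercept and linear-slope SDs, their correlation, and
#' the residual SD, all on the T-score scale of the outcome.
#'
#' @param gamma named numeric vector of the 25 fixed effects; names must be
#'   exactly `design_colnames()` (any order; stored in canonical order).
#' @param sd_u0 between-person intercept SD (> 0 allowed to be 0 for
#'   degenerate no-noise scenarios).
#' @param sd_u1 between-person linear-slope SD.
#' @param rho intercept--slope correlation in `[-1, 1]`.
#' @param sd_resid residual SD.
#' @return object of class `true_parameters`.
#' @export
true_parameters <- function(gamma, sd_u0, sd_u1, rho, sd_resid) {
  nm <- design_colnames()
  if (is.null(names(gamma)) || length(gamma) != 25L ||
      !setequal(names(gamma), nm))
    stopf("'gamma' must be a named vector with exactly the 25 design columns")
  gamma <- gamma[nm]
  for (v in c("sd_u0", "sd_u1", "sd_resid")) {
    val <- get(v)
    assert_scalar_number(val, v)
    if (val < 0) stopf("'%s' must be non-negative", v)
  }
  assert_scalar_number(rho, "rho")
  if (abs(rho) > 1) stopf("'rho' must lie in [-1, 1]")
  structure(list(gamma = gamma, sd_u0 = sd_u0, sd_u1 = sd_u1,
                 rho = rho, sd_resid = sd_resid),
            class = "true_parameters")
}

#' Reference truth sets for the three cognitive outcomes
#'
#' Returns a `true_parameters` object with literature-based values for one
#' of the three outcomes: visuospatial ability (`"va"`), semantic knowledge
#' (`"sk"`) or episodic memory (`"em"`).  These serve as realistic defaults
#' for the synthetic generator: level around 47--49 T, linear decline up to
#' about 0.3 T/year of age for visuospatial ability, small accelerating
#' decline, positive education effects on level, and an essentially null
#' education-by-slope effect.
#'
#' The quadratic-slope block is stored in per-decade-squared units and
#' converted to raw per-year-squared units (divided by 100) to match this
#' package's raw-residual quadratic basis: an acceleration of -0.142
#' T/decade^2 is -0.00142 T/year^2, giving realistic sub-T-unit curvature
#' over the observed age span rather than the tens of T-units a raw
#' reading would imply.
#'
#' @param outcome one of `"va"`, `"sk"`, `"em"`.
#' @return a [true_parameters()] object.
#' @export
default_truth <- function(outcome = c("va", "sk", "em")) {
  outcome <- match.arg(outcome)
  nm <- design_colnames()
  tab <- switch(outcome,
    va = list(
      ic = c(48.441, 0.096, 0.655, -1.444, -0.588, -0.007, -0.034, -0.004, -0.001),
      ls = c(-0.308, -0.001, -0.001, -0.009, -0.001, 0.000, -0.002, 0.000),
      qs = c(-0.142, 0.000, -0.008, 0.029, 0.000, -0.002, 0.004, 0.000),
      re = c(6.887, 0.042, -0.514, 4.330)),
    sk = list(
      ic = c(48.758, 0.031, 1.295, 2.649, 0.461, -0.019, 0.059, -0.048, -0.034),
      ls = c(-0.021, -0.006, 0.001, 0.028, 0.000, 0.005, -0.008, -0.001),
      qs = c(-0.150, 0.002, 0.001, 0.018, 0.000, 0.000, -0.010, 0.000),
      re = c(7.213, 0.143, 0.490, 3.821)),
    em = list(
      ic = c(47.294, 0.248, 0.445, 1.835, -0.959, -0.001, -0.116, 0.344, -0.006),
      ls = c(-0.198, 0.001, 0.006, -0.030, -0.001, -0.004, 0.002, 0.000),
      qs = c(-0.121, 0.002, -0.013, -0.074, 0.001, 0.001, 0.011, 0.000),
      re = c(5.703, 0.075, 0.494, 6.434)))
  gamma <- stats::setNames(c(tab$ic, tab$ls, tab$qs / 100), nm)
  true_parameters(gamma, sd_u0 = tab$re[1], sd_u1 = tab$re[2],
                  rho = tab$re[3], sd_resid = tab$re[4])
}

#' Flatten ground truth into a named parameter vector
#'
#' Produces a flat named vector with one entry per model parameter (25
#' fixed effects followed by `sd_u0`, `sd_u1`, `rho`, `sd_resid`) in the
#' same order as the columns of posterior draws, for recovery scoring.
#'
#' @param truth a [true_parameters()] object.
#' @return named numeric vector of length 29.
#' @seealso [as_true_parameters()] for the inverse.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "true_parameters"))
  c(truth$gamma,
    sd_u0 = truth$sd_u0, sd_u1 = truth$sd_u1,
    rho = truth$rho, sd_resid = truth$sd_resid)
}

#' Re-assemble ground truth from a flat parameter vector
#'
#' @param x named numeric vector of length 29 as produced by [truth_table()].
#' @return a [true_parameters()] object.
#' @export
as_true_parameters <- function(x) {
  nm <- param_names()
  if (is.null(names(x)) || !setequal(names(x), nm))
    stopf("'x' must carry exactly the 29 model parameter names")
  x <- x[nm]
  true_parameters(x[design_colnames()],
                  sd_u0 = unname(x["sd_u0"]), sd_u1 = unname(x["sd_u1"]),
                  rho = unname(x["rho"]), sd_resid = unname(x["sd_resid"]))
}

#' @export
print.study_design <- function(x, ...) {
  cat("Cohort-sequential study design\n")
  cat(sprintf("  cohorts: %s\n", paste(x$cohort_birth_years, collapse = ", ")))
  cat(sprintf("  samples: %s (entry waves %s)\n",
              paste(names(x$sample_entry_waves), collapse = ", "),
              paste(x$sample_entry_waves, collapse = ", ")))
  cat(sprintf("  waves: %s\n", paste(x$wave_years, collapse = ", ")))
  cat(sprintf("  persons per cell: %d; dropout hazard: %.2f\n",
              x$persons_per_cell, x$dropout_hazard))
  invisible(x)
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("Ground-truth growth-model parameters (T-score units)\n")
  print(round(truth_table(x), 4))
  invisible(x)
}
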