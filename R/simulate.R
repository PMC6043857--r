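#' Default set of ground truths for all three outcomes
#'
#' Named list of [default_truth()] objects for visuospatial ability,
#' semantic knowledge and episodic memory, in the column order of the
#' long-format dataset.
#'
#' @return named list of `true_parameters`.
#' @export
default_truths <- function() {
  list(va = default_truth("va"), sk = default_truth("sk"),
       em = default_truth("em"))
}

#' Generate a synthetic cohort-sequential longitudinal dataset
#'
#' Creates person-period records that emulate a two-sample accelerated
#' longitudinal study: for every sample and every birth cohort,
#' `persons_per_cell` individuals are created, attend from their sample's
#' entry wave onward, and drop out permanently after any attended wave with
#' probability `design$dropout_hazard` (monotone missingness).  Outcome
#' scores follow the hierarchical growth model: person-level random
#' intercepts and linear age slopes drawn from a bivariate Normal, a fixed
#' quadratic age trend, and Normal residual noise, all on the centered and
#' orthogonalized covariates.  The centered covariates and the orthogonal
#' quadratic age basis are computed on the generated (post-dropout) rows
#' with the supplied centering constants, so preparing the data with the
#' same constants and no exclusions reproduces the generating design matrix
#' exactly.
#'
#' @param design a [study_design()].
#' @param truth a [true_parameters()] object (single outcome, stored in a
#'   column named `y`) or a named list of them, one per outcome column;
#'   defaults to [default_truths()] giving `va`, `sk` and `em` columns with
#'   independent person effects per outcome.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param centers centering constants (years) for age, cohort and education
#'   used when evaluating the model's linear predictor.
#' @param age_jitter if `TRUE`, adds a person-level uniform offset on
#'   `[-2, 2]` years to all of a person's ages; default off, so age is the
#'   integer `test_year - birth_year`.
#' @param education_noise if `TRUE`, per-wave reported education equals the
#'   person's education plus independent -1/0/+1 year reporting noise;
#'   default off.
#' @return a `data.frame` with columns `person_id`, `birth_year`, `sex`
#'   (0 male / 1 female), `sample`, `wave`, `test_year`, `education`
#'   (per-wave report, years) and one column per outcome.  Attributes
#'   `centers` and `basis_coef` record the covariate centers and the
#'   projection coefficients of the quadratic age basis.
#' @export
generate_cohort <- function(design, truth = default_truths(), seed,
                            centers = list(age = 62.9, cohort = 1933,
                                           education = 10.2),
                            age_jitter = FALSE, education_noise = FALSE) {
  stopifnot(inherits(design, "study_design"))
  if (inherits(truth, "true_parameters")) truth <- list(y = truth)
  if (!is.list(truth) || length(truth) == 0L || is.null(names(truth)) ||
      !all(vapply(truth, inherits, logical(1), "true_parameters")))
    stopf("'truth' must be a true_parameters object or a named list of them")
  if (missing(seed)) stopf("'seed' is required")
  if (design$persons_per_cell < 1L) stopf("'persons_per_cell' must be positive")
  set.seed(as.integer(seed))

  samples <- names(design$sample_entry_waves)
  cells <- expand.grid(cohort = design$cohort_birth_years,
                       sample = samples, stringsAsFactors = FALSE)
  n <- nrow(cells) * design$persons_per_cell
  person <- data.frame(
    person_id = sprintf("P%05d", seq_len(n)),
    birth_year = rep(cells$cohort, each = design$persons_per_cell),
    sample = rep(cells$sample, each = design$persons_per_cell),
    stringsAsFactors = FALSE
  )
  person$sex <- stats::rbinom(n, 1L, design$female_fraction)
  edu <- round(stats::rnorm(n, design$education_mean, design$education_sd))
  person$education <- pmin(pmax(edu, design$education_min), design$education_max)
  person$entry <- design$sample_entry_waves[person$sample]
  jitter_off <- if (age_jitter) stats::runif(n, -2, 2) else numeric(n)

  # attendance with permanent dropout after each attended wave
  n_waves <- length(design$wave_years)
  k <- n_waves - person$entry + 1L        # waves available to each person
  rows <- data.frame(
    row_person = rep(seq_len(n), k),
    wave = unlist(lapply(seq_len(n), function(i)
      seq(person$entry[i], n_waves)), use.names = FALSE)
  )
  wpos <- sequence(k)                      # within-person wave position
  td <- stats::runif(nrow(rows))
  drop_flag <- td < design$dropout_hazard
  cum_prev <- stats::ave(drop_flag, rows$row_person, FUN = cumsum) - drop_flag
  rows <- rows[wpos == 1L | cum_prev == 0, , drop = FALSE]

  i <- rows$row_person
  out <- data.frame(
    person_id = person$person_id[i],
    birth_year = person$birth_year[i],
    sex = person$sex[i],
    sample = person$sample[i],
    wave = rows$wave,
    test_year = design$wave_years[rows$wave],
    stringsAsFactors = FALSE
  )
  out$education <- person$education[i]
  if (education_noise)
    out$education <- out$education + sample(c(-1L, 0L, 1L), nrow(out),
                                            replace = TRUE)
  age <- out$test_year - out$birth_year + jitter_off[i]

  # linear predictor pieces on the generator's own rows
  age_c <- age - centers$age
  basis <- orthogonal_age_basis(age_c)
  sample_code <- as.numeric(out$sample == samples[min(2L, length(samples))])
  if (length(samples) == 1L) sample_code <- rep(0, nrow(out))
  X <- build_design(age_lin = basis$lin, age_quad = basis$quad,
                    cohort_c = out$birth_year - centers$cohort,
                    edu_c = person$education[i] - centers$education,
                    sex = out$sex, sample_code = sample_code)

  pid <- match(i, unique(i))
  np <- length(unique(i))
  for (o in names(truth)) {
    tr <- truth[[o]]
    z1 <- stats::rnorm(np); z2 <- stats::rnorm(np)
    u0 <- tr$sd_u0 * z1
    u1 <- tr$sd_u1 * (tr$rho * z1 + sqrt(max(0, 1 - tr$rho^2)) * z2)
    eps <- tr$sd_resid * stats::rnorm(nrow(out))
    out[[o]] <- drop(X %*% tr$gamma) + u0[pid] + u1[pid] * basis$lin + eps
  }
  attr(out, "centers") <- centers
  attr(out, "basis_coef") <- basis$coef
  rownames(out) <- NULL
  out
}

#' Thin an existing longitudinal dataset by monotone attrition
#'
#' Each person independently drops out permanently after each attended wave
#' with probability `hazard`; the first attended wave is never removed, and
#' missingness stays monotone.
#'
#' @param data long-format person-period `data.frame` with `person_id` and
#'   `wave` columns.
#' @param hazard per-wave dropout probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the dataset with dropped rows removed.
#' @export
apply_attrition <- function(data, hazard, seed) {
  assert_probability(hazard, "hazard")
  if (missing(seed)) stopf("'seed' is required")
  set.seed(as.integer(seed))
  ord <- order(data$person_id, data$wave)
  data <- data[ord, , drop = FALSE]
  pid <- match(data$person_id, unique(data$person_id))
  wpos <- stats::ave(rep(1, nrow(data)), pid, FUN = cumsum)
  td <- stats::runif(nrow(data))
  drop_flag <- td < hazard
  cum_prev <- stats::ave(drop_flag, pid, FUN = cumsum) - drop_flag
  res <- data[wpos == 1 | cum_prev == 0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a longitudinal dataset as long-format CSV
#'
#' Header: `person_id,birth_year,sex,sample,wave,test_year,education,va,sk,em`;
#' missing values are written as empty fields.  Outcome columns absent from
#' the data are written empty.
#'
#' @param data dataset as returned by [generate_cohort()].
#' @param path output file path.
#' @export
write_cohort_csv <- function(data, path) {
  cols <- c("person_id", "birth_year", "sex", "sample", "wave",
            "test_year", "education", "va", "sk", "em")
  for (cc in setdiff(cols, names(data))) data[[cc]] <- NA_real_
  utils::write.table(data[cols], path, sep = ",", row.names = FALSE,
                     na = "", quote = FALSE)
  invisible(path)
}

#' Read a long-format longitudinal CSV
#'
#' @param path file written by [write_cohort_csv()] (empty fields are
#'   missing values).
#' @return `data.frame` in the long person-period format.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
}
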