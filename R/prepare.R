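#' Data-preparation configuration
#'
#' Centering constants, T-standardization targets, education admissibility
#' bounds and cohort exclusions used when turning raw person-period records
#' into the model's design matrices.  Defaults are the conventional values
#' for this design: age centered at 62.9 years, cohort at birth year 1933,
#' education at 10.2 years; T-scores anchored at mean 50 / SD 10 of the
#' first measurement occasion; education admissible in (6, 25] years;
#' earliest (1908--1910) and latest (1958--1960) cohort bands excluded.
#'
#' @param age_center years; subtracted from age at testing.
#' @param cohort_center calendar year subtracted from birth year.
#' @param education_center years subtracted from derived education.
#' @param t_mean,t_sd target mean and SD of the T-standardized outcome.
#' @param education_max_allowed persons reporting more than this are removed.
#' @param education_min_allowed persons reporting less than this are removed
#'   (default 6 years, a proxy for less-than-compulsory schooling).
#' @param excluded_cohorts list of birth-year bands `c(first, last)`;
#'   persons born within any band are removed.
#' @param recompute_centers_from_data if `TRUE`, the three centers are
#'   replaced by the retained rows' own means (useful for synthetic designs
#'   whose support differs from the default constants).
#' @param standardize if `FALSE`, the outcome is used on its raw scale
#'   instead of being T-standardized; intended for synthetic data already
#'   generated on the T scale, where re-standardization would rescale the
#'   generating parameters by a data-dependent factor.
#' @return object of class `prep_config`.
#' @export
prep_config <- function(age_center = 62.9,
                        cohort_center = 1933,
                        education_center = 10.2,
                        t_mean = 50,
                        t_sd = 10,
                        education_max_allowed = 25,
                        education_min_allowed = 6,
                        excluded_cohorts = list(c(1908, 1910), c(1958, 1960)),
                        recompute_centers_from_data = FALSE,
                        standardize = TRUE) {
  if (t_sd <= 0) stopf("'t_sd' must be positive")
  if (education_min_allowed >= education_max_allowed)
    stopf("'education_min_allowed' must be below 'education_max_allowed'")
  structure(list(age_center = age_center, cohort_center = cohort_center,
                 education_center = education_center, t_mean = t_mean,
                 t_sd = t_sd,
                 education_max_allowed = education_max_allowed,
                 education_min_allowed = education_min_allowed,
                 excluded_cohorts = excluded_cohorts,
                 recompute_centers_from_data = recompute_centers_from_data,
                 standardize = standardize),
            class = "prep_config")
}

#' Person-level education from per-wave reports
#'
#' Education is defined as the maximum number of years reported over the
#' waves; missing reports are ignored, and a person with no report at any
#' wave gets `NA`.
#'
#' @param reports numeric vector of per-wave reported years (may contain
#'   `NA`).
#' @return scalar years, or `NA` if all reports are missing.
#' @export
derive_education <- function(reports) {
  if (!is.numeric(reports) && !all(is.na(reports)))
    stopf("'reports' must be numeric")
  if (any(reports < 0, na.rm = TRUE))
    stopf("negative education reports are invalid")
  if (all(is.na(reports))) return(NA_real_)
  max(reports, na.rm = TRUE)
}

#' Apply person-level exclusion filters
#'
#' Removes, in order: (a) persons born in an excluded cohort band, (b)
#' persons with education missing at all waves, (c) persons whose derived
#' education exceeds `education_max_allowed`, and (d) persons whose derived
#' education falls below `education_min_allowed`.  Each person is counted
#' once, under the first rule that fires.
#'
#' @param data long-format dataset (see [generate_cohort()]).
#' @param cfg a [prep_config()].
#' @return list with `data` (retained rows) and `report`, a named integer
#'   vector of per-rule removal counts
#'   (`excluded_cohort`, `education_missing`, `education_above_max`,
#'   `education_below_min`).
#' @export
apply_exclusions <- function(data, cfg = prep_config()) {
  ids <- unique(data$person_id)
  by <- data$birth_year[match(ids, data$person_id)]
  f <- factor(data$person_id, levels = ids)
  edu <- as.numeric(tapply(data$education, f, derive_education))

  in_band <- rep(FALSE, length(ids))
  for (b in cfg$excluded_cohorts)
    in_band <- in_band | (by >= b[1] & by <= b[2])
  rule <- rep(0L, length(ids))
  rule[in_band] <- 1L
  rule[rule == 0L & is.na(edu)] <- 2L
  rule[rule == 0L & !is.na(edu) & edu > cfg$education_max_allowed] <- 3L
  rule[rule == 0L & !is.na(edu) & edu < cfg$education_min_allowed] <- 4L

  report <- c(excluded_cohort = sum(rule == 1L),
              education_missing = sum(rule == 2L),
              education_above_max = sum(rule == 3L),
              education_below_min = sum(rule == 4L))
  keep <- ids[rule == 0L]
  res <- data[data$person_id %in% keep, , drop = FALSE]
  rownames(res) <- NULL
  list(data = res, report = report)
}

#' T-standardize scores on first-occasion statistics
#'
#' Scores are linearly rescaled to `T = t_mean + t_sd * (raw - m) / s`,
#' where `m` and `s` are the mean and population SD (divide by n) of the
#' non-missing scores at the first measurement occasion, i.e. the smallest
#' wave label present.  The same transform is applied to all waves.
#'
#' @param scores numeric raw scores (may contain `NA`).
#' @param waves wave labels, same length as `scores`.
#' @param cfg a [prep_config()] supplying `t_mean` and `t_sd`.
#' @return list with `t` (transformed scores), `baseline_mean`,
#'   `baseline_sd` and `baseline_wave`.
#' @export
t_standardize <- function(scores, waves, cfg = prep_config()) {
  if (length(scores) != length(waves))
    stopf("'scores' and 'waves' must have equal length")
  w0 <- min(waves[!is.na(scores)])
  base <- scores[waves == w0 & !is.na(scores)]
  if (length(base) < 2L)
    stopf("first occasion must have at least 2 non-missing scores")
  m <- mean(base)
  s <- pop_sd(base)
  if (s == 0)
    stopf("first-occasion scores have zero SD; T-standardization undefined")
  list(t = cfg$t_mean + cfg$t_sd * (scores - m) / s,
       baseline_mean = m, baseline_sd = s, baseline_wave = w0)
}

#' Center age, cohort and education covariates
#'
#' @param age years at testing.
#' @param cohort birth year.
#' @param education years of education.
#' @param cfg a [prep_config()] supplying the three centers.
#' @return list with `age_c`, `cohort_c`, `edu_c`.
#' @export
center_covariates <- function(age, cohort, education, cfg = prep_config()) {
  list(age_c = age - cfg$age_center,
       cohort_c = cohort - cfg$cohort_center,
       edu_c = education - cfg$education_center)
}

#' Orthogonal quadratic age basis
#'
#' Decomposes age into a linear term (the centered age itself) and a
#' quadratic term orthogonalized against the constant and linear terms over
#' all supplied rows: `age_quad` is the residual of `age_c^2` after
#' least-squares projection onto `span{1, age_c}` (observation-weighted
#' Gram--Schmidt, pooled over rows).  By construction
#' `sum(age_quad) = sum(age_quad * age_lin) = 0` to numerical tolerance.
#'
#' @param ages_c centered ages over all retained person-period rows.
#' @return list with `lin`, `quad` and `coef` (`c(c0, c1)` such that
#'   `quad = ages_c^2 - c0 - c1 * ages_c`).
#' @export
orthogonal_age_basis <- function(ages_c) {
  if (length(unique(ages_c)) < 3L)
    stopf("need at least 3 distinct ages to identify a quadratic basis")
  q <- ages_c^2
  M <- cbind(1, ages_c)
  MtM <- crossprod(M)
  cf <- drop(solve(MtM, crossprod(M, q)))
  quad <- q - cf[1] - cf[2] * ages_c
  # one refinement pass: removes the O(eps * ||q||) residual the first
  # projection leaves on long, large-magnitude rowsets
  cf2 <- drop(solve(MtM, crossprod(M, quad)))
  quad <- quad - cf2[1] - cf2[2] * ages_c
  cf <- cf + cf2
  list(lin = ages_c, quad = quad,
       coef = c(c0 = unname(cf[1]), c1 = unname(cf[2])))
}

#' Assemble the 25-column fixed-effects design matrix
#'
#' Intercept block: `{1, cohort_c, edu_c, sex, sample_code}` plus the
#' cohort/education/sex two- and three-way interactions.  Linear-slope
#' block: `age_lin` times the same covariates without sample.
#' Quadratic-slope block: `age_quad` times the same eight terms.  Sample
#' appears as a main effect only.
#'
#' @param age_lin,age_quad orthogonal age basis values per row.
#' @param cohort_c,edu_c centered cohort and education per row.
#' @param sex 0/1 per row.
#' @param sample_code 0/1 per row.
#' @return numeric matrix with 25 named columns (see [design_colnames()]).
#' @export
build_design <- function(age_lin, age_quad, cohort_c, edu_c, sex, sample_code) {
  args <- list(age_lin, age_quad, cohort_c, edu_c, sex, sample_code)
  if (anyNA(unlist(args))) stopf("design covariates must be complete")
  n <- length(age_lin)
  one <- rep(1, n)
  covs <- cbind(cohort_c, edu_c, sex,
                cohort_c * edu_c, cohort_c * sex, edu_c * sex,
                cohort_c * edu_c * sex)
  X <- cbind(one, covs[, 1:3], sample_code, covs[, 4:7],
             age_lin, age_lin * covs,
             age_quad, age_quad * covs)
  colnames(X) <- design_colnames()
  X
}

#' Prepare a longitudinal dataset for model fitting
#'
#' Applies the exclusion filters, derives person-level education as the
#' maximum over waves, drops rows with a missing outcome (observed rows
#' only enter the likelihood; no listwise deletion), optionally
#' T-standardizes the outcome on first-occasion statistics, centers the
#' covariates, builds the pooled orthogonal age basis and the 25-column
#' fixed-effects design matrix.  The random-effects design per person has
#' columns `(1, age_lin)`.
#'
#' @param data long-format dataset (from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param outcome name of the outcome column to model.
#' @param cfg a [prep_config()].
#' @return object of class `prepared_dataset`: a list with `data` (rows of
#'   person id, wave, outcome `y`, centered covariates and basis values),
#'   `X` (fixed-effects matrix), `person` (integer person index per row),
#'   `person_ids`, `outcome`, `centers`, `basis_coef`, `baseline`
#'   (first-occasion mean/SD or `NULL`), `exclusions` and `cfg`.
#' @export
prepare_dataset <- function(data, outcome, cfg = prep_config()) {
  need <- c("person_id", "birth_year", "sex", "sample", "wave",
            "test_year", "education", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("dataset lacks columns: %s", paste(miss, collapse = ", "))

  ex <- apply_exclusions(data, cfg)
  d <- ex$data
  ids <- unique(d$person_id)
  f <- factor(d$person_id, levels = ids)
  edu_person <- as.numeric(tapply(d$education, f, derive_education))
  d$edu_derived <- edu_person[match(d$person_id, ids)]

  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  if (nrow(d) == 0L) stopf("no rows with observed '%s' remain", outcome)
  d <- d[order(d$person_id, d$wave), , drop = FALSE]

  age <- d$test_year - d$birth_year
  if (isTRUE(cfg$recompute_centers_from_data)) {
    cfg$age_center <- mean(age)
    cfg$cohort_center <- mean(d$birth_year)
    cfg$education_center <- mean(d$edu_derived)
  }

  baseline <- NULL
  y <- d[[outcome]]
  if (isTRUE(cfg$standardize)) {
    ts <- t_standardize(y, d$wave, cfg)
    y <- ts$t
    baseline <- c(mean = ts$baseline_mean, sd = ts$baseline_sd,
                  wave = ts$baseline_wave)
  }

  cc <- center_covariates(age, d$birth_year, d$edu_derived, cfg)
  basis <- orthogonal_age_basis(cc$age_c)
  slabs <- sort(unique(data$sample))
  if (length(slabs) > 2L)
    stopf("at most two sample labels are supported")
  sample_code <- as.numeric(d$sample == slabs[length(slabs)])
  if (length(slabs) == 1L) sample_code <- rep(0, nrow(d))

  X <- build_design(age_lin = basis$lin, age_quad = basis$quad,
                    cohort_c = cc$cohort_c, edu_c = cc$edu_c,
                    sex = d$sex, sample_code = sample_code)
  person <- match(d$person_id, unique(d$person_id))

  out <- data.frame(person_id = d$person_id, wave = d$wave, age = age,
                    y = y, age_c = cc$age_c, age_lin = basis$lin,
                    age_quad = basis$quad, cohort_c = cc$cohort_c,
                    edu_c = cc$edu_c, sex = d$sex,
                    sample_code = sample_code, stringsAsFactors = FALSE)
  structure(list(data = out, X = X, person = person,
                 person_ids = unique(d$person_id), outcome = outcome,
                 centers = c(age = cfg$age_center, cohort = cfg$cohort_center,
                             education = cfg$education_center),
                 basis_coef = basis$coef, baseline = baseline,
                 exclusions = ex$report, cfg = cfg),
            class = "prepared_dataset")
}

#' @export
print.prepared_dataset <- function(x, ...) {
  cat(sprintf("Prepared dataset: outcome '%s', %d rows, %d persons\n",
              x$outcome, nrow(x$data), length(x$person_ids)))
  cat(sprintf("  centers: age %.2f, cohort %.1f, education %.2f\n",
              x$centers["age"], x$centers["cohort"], x$centers["education"]))
  if (!is.null(x$baseline))
    cat(sprintf("  T-anchor: first-occasion mean %.3f, SD %.3f (wave %g)\n",
                x$baseline["mean"], x$baseline["sd"], x$baseline["wave"]))
  cat("  exclusions: ", paste(names(x$exclusions), x$exclusions,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write prepared data and design matrix as CSV
#'
#' Writes the long prepared rows to `<path>` and, when `design_path` is
#' given, the 25-column fixed-effects matrix (with header) alongside.
#'
#' @param prepared a [prepare_dataset()] result.
#' @param path CSV path for the prepared rows.
#' @param design_path optional CSV path for the design matrix.
#' @export
write_prepared_csv <- function(prepared, path, design_path = NULL) {
  utils::write.csv(prepared$data, path, row.names = FALSE, na = "")
  if (!is.null(design_path))
    utils::write.csv(as.data.frame(prepared$X, check.names = FALSE),
                     design_path, row.names = FALSE, na = "")
  invisible(path)
}
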