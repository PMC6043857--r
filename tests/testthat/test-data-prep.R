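# Hand-built 10-person fixture exercising every exclusion rule:
# 2 persons in excluded cohort bands, 1 with education missing at all
# waves, 1 reporting 30 years, and 6 clean persons.
exclusion_fixture <- function() {
  mk <- function(id, by, edu) data.frame(
    person_id = id, birth_year = by, sex = 0, sample = "S1",
    wave = 1:5, test_year = seq(1989, 2009, 5),
    education = edu, va = 50, sk = 50, em = 50,
    stringsAsFactors = FALSE)
  rbind(
    mk("E1", 1909, rep(12, 5)),            # rule (a): earliest band
    mk("E2", 1959, rep(12, 5)),            # rule (a): latest band
    mk("E3", 1934, rep(NA_real_, 5)),      # rule (b): education all missing
    mk("E4", 1934, rep(30, 5)),            # rule (c): > 25 years
    do.call(rbind, lapply(1:6, function(i)
      mk(paste0("K", i), 1920 + 5 * i, rep(8 + i, 5))))
  )
}

test_that("exclusion filters reproduce hand-counted removals, in rule order", {
  fx <- exclusion_fixture()
  res <- apply_exclusions(fx, prep_config())
  expect_equal(unname(res$report),
               c(2L, 1L, 1L, 0L))
  expect_equal(names(res$report),
               c("excluded_cohort", "education_missing",
                 "education_above_max", "education_below_min"))
  expect_setequal(unique(res$data$person_id), paste0("K", 1:6))

  # a person fails the first rule that fires: born 1909 AND reporting 30
  # years counts under the cohort rule, not the education rule
  fx2 <- fx
  fx2$education[fx2$person_id == "E1"] <- 30
  res2 <- apply_exclusions(fx2, prep_config())
  expect_equal(unname(res2$report), c(2L, 1L, 1L, 0L))

  # idempotent
  res3 <- apply_exclusions(res$data, prep_config())
  expect_identical(res3$data, res$data)
  expect_equal(sum(res3$report), 0L)

  # low-education rule with the compulsory-schooling floor
  fx3 <- fx
  fx3$education[fx3$person_id == "K1"] <- 4
  res4 <- apply_exclusions(fx3, prep_config())
  expect_equal(unname(res4$report), c(2L, 1L, 1L, 1L))
})

test_that("education derivation takes the maximum over non-missing reports", {
  expect_equal(derive_education(c(10, 12, NA, 12, 11)), 12)
  expect_equal(derive_education(c(8, 8, 9, 9, 9)), 9)
  expect_true(is.na(derive_education(rep(NA_real_, 5))))
  expect_error(derive_education(c(10, -1, 12)), "negative")
})

test_that("T-standardization anchors to the first occasion with population SD", {
  cfg <- prep_config()
  # first-occasion raws {0, 10}: mean 5, population SD 5
  ts <- t_standardize(c(0, 10, 10, 7), c(1, 1, 2, 3), cfg)
  expect_equal(ts$baseline_mean, 5)
  expect_equal(ts$baseline_sd, 5)
  expect_equal(ts$t, c(40, 60, 60, 54))

  # score at the first-occasion mean -> 50; one SD above -> 60
  ts2 <- t_standardize(c(1, 3, 2, 9), c(1, 1, 2, 3), cfg)  # m = 2, s = 1
  expect_equal(ts2$t, c(40, 60, 50, 120))

  expect_error(t_standardize(c(5, 5, 5, 8), c(1, 1, 1, 2), cfg), "zero SD")
  # the anchor occasion is the smallest wave present, even if it is not 1
  ts3 <- t_standardize(c(0, 10, 20), c(2, 2, 4), cfg)
  expect_equal(ts3$baseline_wave, 2)
  expect_equal(ts3$t, c(40, 60, 80))
})

test_that("covariate centering subtracts the configured constants", {
  cfg <- prep_config()
  cc <- center_covariates(62.9, 1933, 10.2, cfg)
  expect_equal(unlist(cc), c(age_c = 0, cohort_c = 0, edu_c = 0))
  cc2 <- center_covariates(72.9, 1943, 13.2, cfg)
  expect_equal(unlist(cc2), c(age_c = 10, cohort_c = 10, edu_c = 3))
})

test_that("orthogonal age basis matches exact Gram-Schmidt and is orthogonal", {
  b <- orthogonal_age_basis(c(-1, 0, 1))
  expect_equal(b$quad, c(1 / 3, -2 / 3, 1 / 3))
  expect_equal(b$lin, c(-1, 0, 1))

  # symmetric ages: quad reduces to age^2 - mean(age^2)
  a_sym <- c(-10, -5, 0, 5, 10)
  bs <- orthogonal_age_basis(a_sym)
  expect_equal(bs$quad, a_sym^2 - mean(a_sym^2), tolerance = 1e-10)

  # arbitrary unbalanced ages: orthogonality holds by construction
  set.seed(42)
  for (i in 1:5) {
    ac <- sample(seq(-25, 25, 5), 60, replace = TRUE)
    bu <- orthogonal_age_basis(ac)
    expect_lt(abs(sum(bu$quad)), 1e-8)
    expect_lt(abs(sum(bu$quad * bu$lin)), 1e-8)
  }
  expect_error(orthogonal_age_basis(c(1, 1, 2)), "3 distinct")
})

test_that("design matrix has the 25 labelled columns with sample as main effect only", {
  n <- 4
  X <- build_design(age_lin = c(-5, 0, 5, 10), age_quad = c(2, -1, -2, 1),
                    cohort_c = rep(10, n), edu_c = rep(2, n),
                    sex = c(0, 1, 0, 1), sample_code = c(0, 0, 1, 1))
  expect_equal(ncol(X), 25L)
  expect_identical(colnames(X), design_colnames())
  expect_false(any(grepl("Sample", colnames(X)[10:25])))
  expect_equal(sum(grepl("^LS", colnames(X))), 8L)
  expect_equal(sum(grepl("^QS", colnames(X))), 8L)
  # spot-check a three-way slope interaction entry
  expect_equal(unname(X[4, "LS x Cohort x Education x Sex"]), 10 * 10 * 2 * 1)
  expect_equal(unname(X[2, "QS"]), -1)
  expect_error(build_design(c(1, NA), c(1, 1), c(0, 0), c(0, 0),
                            c(0, 0), c(0, 0)), "complete")
})

test_that("a zero-covariate male row activates only intercept and QS columns", {
  # age_c = 0 rows still carry a nonzero orthogonalized quadratic value
  b <- orthogonal_age_basis(c(-5, 0, 5, 10))
  i <- which(b$lin == 0)
  X <- build_design(age_lin = b$lin, age_quad = b$quad,
                    cohort_c = rep(0, 4), edu_c = rep(0, 4),
                    sex = rep(0, 4), sample_code = rep(0, 4))
  nz <- colnames(X)[X[i, ] != 0]
  expect_setequal(nz, c("Intercept", "QS"))
  expect_false(b$quad[i] == 0)
})

test_that("prepared first-occasion T-scores hit mean 50, SD 10 to machine precision", {
  des <- small_design(12L, dropout_hazard = 0.1)
  dat <- generate_cohort(des, seed = 17)
  prep <- prepare_dataset(dat, "va",
                          prep_config(excluded_cohorts = list(),
                                      education_min_allowed = 0))
  w0 <- prep$baseline["wave"]
  base <- prep$data$y[prep$data$wave == w0]
  expect_equal(mean(base), 50, tolerance = 1e-12)
  expect_equal(sqrt(mean((base - 50)^2)), 10, tolerance = 1e-12)
})

test_that("generator/prep round trip reproduces noise-free outcomes through the design matrix", {
  des <- small_design(6L, dropout_hazard = 0.2)
  tr <- default_truth("sk")
  tr0 <- true_parameters(tr$gamma, 0, 0, 0, 0)
  dat <- generate_cohort(des, list(sk = tr0), seed = 23)
  prep <- prepare_dataset(dat, "sk", synthetic_prep())
  expect_equal(prep$data$y, drop(prep$X %*% tr$gamma), tolerance = 1e-12)
  # and the quadratic basis is orthogonal on the retained rows
  expect_lt(abs(sum(prep$data$age_quad)), 1e-8)
  expect_lt(abs(sum(prep$data$age_quad * prep$data$age_lin)), 1e-8)
})

test_that("recomputed centers equal the retained-row means", {
  des <- small_design(6L)
  dat <- generate_cohort(des, seed = 29)
  cfg <- prep_config(standardize = FALSE, excluded_cohorts = list(),
                     education_min_allowed = 0,
                     recompute_centers_from_data = TRUE)
  prep <- prepare_dataset(dat, "em", cfg)
  age <- prep$data$age
  expect_equal(unname(prep$centers["age"]), mean(age))
  expect_equal(mean(prep$data$age_c), 0, tolerance = 1e-10)
  expect_equal(mean(prep$data$cohort_c), 0, tolerance = 1e-10)
})
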