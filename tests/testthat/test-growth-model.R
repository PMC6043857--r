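# Tiny prepared fixture: 3 persons x 3 waves, modest effects, built from
# the generator so the design matrix is internally consistent.
tiny_prepared <- function(seed = 2, sd_u0 = 2, sd_u1 = 0.3, rho = 0.4,
                          sd_resid = 1.5) {
  des <- study_design(cohort_birth_years = c(1924, 1934, 1944),
                      persons_per_cell = 1L,
                      sample_entry_waves = c(S1 = 1L),
                      wave_years = c(1989, 1994, 1999),
                      dropout_hazard = 0,
                      education_min = 6, education_max = 25)
  tr <- true_parameters(
    stats::setNames(c(50, 0.1, 0.5, rep(0, 6), -0.3, rep(0, 7),
                      -0.05, rep(0, 7)), design_colnames()),
    sd_u0 = sd_u0, sd_u1 = sd_u1, rho = rho, sd_resid = sd_resid)
  dat <- generate_cohort(des, list(va = tr), seed = seed)
  list(prep = prepare_dataset(dat, "va", synthetic_prep()), truth = tr)
}

test_that("marginal likelihood matches the Gauss-Hermite quadrature oracle", {
  fx <- tiny_prepared()
  params <- truth_table(fx$truth)
  ll <- log_likelihood(params, fx$prep)
  ll_gh <- gh_loglik(params, fx$prep, n_nodes = 30)
  expect_lt(abs(ll - ll_gh), 1e-6)

  # a second parameter point away from the truth
  params2 <- params
  params2["LS"] <- 0.2
  params2["sd_u1"] <- 0.6
  params2["rho"] <- -0.5
  expect_lt(abs(log_likelihood(params2, fx$prep) -
                  gh_loglik(params2, fx$prep, 30)), 1e-6)
})

test_that("likelihood limits: no random effects reduce to iid normal, and a single standardized residual", {
  fx <- tiny_prepared()
  params <- truth_table(fx$truth)
  params["sd_u0"] <- 0
  params["sd_u1"] <- 0
  params["rho"] <- 0
  mu <- drop(fx$prep$X %*% params[design_colnames()])
  direct <- sum(stats::dnorm(fx$prep$data$y, mu, params["sd_resid"],
                             log = TRUE))
  expect_equal(log_likelihood(params, fx$prep), direct, tolerance = 1e-10)

  # one person, one observation, y = x'gamma, unit residual SD
  one <- fx$prep
  one$data <- one$data[1, , drop = FALSE]
  one$X <- one$X[1, , drop = FALSE]
  one$person <- 1L
  params1 <- params
  params1["sd_resid"] <- 1
  one$data$y <- drop(one$X %*% params1[design_colnames()])
  expect_equal(log_likelihood(params1, one), -0.5 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to row permutations and matches the fast path", {
  fx <- tiny_prepared()
  params <- truth_table(fx$truth)
  ll <- log_likelihood(params, fx$prep)

  set.seed(4)
  perm <- sample(nrow(fx$prep$data))
  shuffled <- fx$prep
  shuffled$data <- shuffled$data[perm, , drop = FALSE]
  shuffled$X <- shuffled$X[perm, , drop = FALSE]
  shuffled$person <- shuffled$person[perm]
  expect_lt(abs(log_likelihood(params, shuffled) - ll), 1e-10)

  ss <- cogdecline:::suff_stats(fx$prep)
  rs <- cogdecline:::residual_stats(ss, params[design_colnames()])
  fast <- cogdecline:::profile_loglik(ss, rs$rss, rs$d1, rs$d2,
                                      params["sd_u0"], params["sd_u1"],
                                      params["rho"], params["sd_resid"])
  expect_lt(abs(fast - ll), 1e-8)
})

test_that("log prior follows the specified families and support", {
  pr <- prior_spec(sigma_focal = 0.017)
  tr <- default_truth("em")
  p <- truth_table(tr)

  # focal contribution at zero is the normal density at its mean
  p0 <- p
  p0["LS x Education"] <- 0
  expect_equal(log_prior(p0, pr) - log_prior(p0, prior_spec(sigma_focal = 1)),
               -log(0.017 * sqrt(2 * pi)) - (-log(sqrt(2 * pi))),
               tolerance = 1e-12)

  # flat LKJ(1): changing rho inside (-1, 1) changes nothing
  pa <- p; pa["rho"] <- 0.2
  pb <- p; pb["rho"] <- -0.7
  expect_equal(log_prior(pa, pr), log_prior(pb, pr))

  # out-of-support scale gives log-zero, not an error
  pc <- p; pc["sd_resid"] <- -1
  expect_identical(log_prior(pc, pr), -Inf)

  # full value against a direct sum
  direct <- sum(stats::dnorm(p[1:25], c(50, rep(0, 24)),
                             c(20, rep(3, 10), 0.017, rep(3, 13)),
                             log = TRUE)) +
    sum(log(2) + stats::dcauchy(p[c("sd_u0", "sd_u1", "sd_resid")],
                                0, 10, log = TRUE)) + log(0.5)
  expect_equal(log_prior(p, pr), direct, tolerance = 1e-12)
})

test_that("split-chain rhat flags separated chains and passes iid ones", {
  set.seed(7)
  same <- matrix(rnorm(8000), ncol = 4)
  expect_lt(rhat(same), 1.01)

  apart <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(rhat(apart), 3)

  const <- matrix(5, nrow = 100, ncol = 4)
  expect_identical(rhat(const), 1.0)

  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("HDI and MAP behave on known shapes", {
  set.seed(11)
  x <- rnorm(50000)
  h <- hdi(x)
  expect_lt(abs(h["lower"] + 1.96), 0.08)
  expect_lt(abs(h["upper"] - 1.96), 0.08)
  expect_lt(abs(map_estimate(x)), 0.1)

  # exponential: HDI is left-anchored and shorter than equal-tailed
  e <- rexp(20000)
  he <- hdi(e)
  eq <- stats::quantile(e, c(0.025, 0.975))
  expect_lt(he["lower"], stats::quantile(e, 0.01))
  expect_lt(he["upper"] - he["lower"], eq[2] - eq[1])

  expect_equal(unname(hdi(rep(3.5, 50))), c(3.5, 3.5))
  expect_equal(map_estimate(rep(3.5, 50)), 3.5)
  expect_error(hdi(x, mass = 1.2), "between 0 and 1")
})

test_that("with no data the sampler reproduces the prior marginals", {
  pr <- prior_spec(sigma_focal = 0.034)
  fit <- suppressWarnings(fit_growth(NULL, pr, chains = 2L, iter = 1500L,
                                     warmup = 300L, seed = 13))
  # gamma is conditionally independent across iterations (exact conditional
  # draws), so a KS test against its prior is clean
  focal <- pooled_draws(fit, "LS x Education")
  ks <- stats::ks.test(focal, "pnorm", 0, 0.034)
  expect_gt(ks$p.value, 0.001)
  ic <- pooled_draws(fit, "Intercept")
  ks2 <- stats::ks.test(ic, "pnorm", 50, 20)
  expect_gt(ks2$p.value, 0.001)
  # slice-sampled scale parameter against the half-Cauchy cdf
  s0 <- pooled_draws(fit, "sd_u0")
  expect_true(all(s0 > 0))
  phc <- function(q) 2 / pi * atan(q / 10)
  emp <- stats::ecdf(s0)
  qs <- c(1, 5, 10, 30, 100)
  expect_lt(max(abs(emp(qs) - phc(qs))), 0.08)
})

test_that("posterior recovers known truth on synthetic data", {
  fx <- tiny_prepared()
  des <- small_design(18L, dropout_hazard = 0.1)
  tr <- default_truth("sk")
  dat <- generate_cohort(des, list(sk = tr), seed = 41)
  prep <- prepare_dataset(dat, "sk", synthetic_prep())
  fit <- suppressWarnings(fit_growth(prep, prior_spec(), chains = 2L,
                                     iter = 600L, warmup = 600L, seed = 19))
  tt <- truth_table(tr)
  for (p in c("Intercept", "LS", "Education")) {
    d <- pooled_draws(fit, p)
    expect_lt(abs(mean(d) - tt[p]) / sd(d), 3)
  }
  expect_true(all(dimnames(fit$draws)[[3]] == param_names()))
  expect_true(all(pooled_draws(fit, "sd_resid") > 0))
  expect_true(all(abs(pooled_draws(fit, "rho")) <= 1))
})

test_that("duplicating the data shrinks the slope posterior SD by about 1/sqrt(2)", {
  des <- small_design(15L)
  tr <- default_truth("va")
  dat <- generate_cohort(des, list(va = tr), seed = 43)
  prep1 <- prepare_dataset(dat, "va", synthetic_prep())

  dat2 <- dat
  dat2$person_id <- paste0(dat$person_id, "b")
  prep2 <- prepare_dataset(rbind(dat, dat2), "va", synthetic_prep())

  f1 <- suppressWarnings(fit_growth(prep1, prior_spec(), chains = 2L,
                                    iter = 500L, warmup = 500L, seed = 3))
  f2 <- suppressWarnings(fit_growth(prep2, prior_spec(), chains = 2L,
                                    iter = 500L, warmup = 500L, seed = 3))
  ratio <- sd(pooled_draws(f2, "LS")) / sd(pooled_draws(f1, "LS"))
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.15)
})

test_that("summaries carry MAP inside the HDI and rhat near 1", {
  fx <- tiny_prepared()
  fit <- suppressWarnings(fit_growth(fx$prep, prior_spec(), chains = 2L,
                                     iter = 400L, warmup = 400L, seed = 5))
  s <- summarize_fit(fit)
  expect_equal(nrow(s), 29L)
  expect_true(all(s$hdi_lower <= s$map & s$map <= s$hdi_upper))
  expect_true(all(s$rhat > 0.97))
  expect_error(summarize_fit(fit, hdi_mass = 0), "between 0 and 1")
})

test_that("draws persist to CSV with a metadata sidecar", {
  fx <- tiny_prepared()
  fit <- suppressWarnings(
    fit_growth(fx$prep, prior_spec(sigma_focal = 0.068), chains = 2L,
               iter = 50L, warmup = 50L, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(fit, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 100L)
  expect_true(all(param_names() %in% names(tab)))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(meta$prior$sigma_focal, 0.068)
  expect_equal(meta$chains, 2L)

  # full round trip back into a growth_fit
  back <- read_draws_csv(path)
  expect_s3_class(back, "growth_fit")
  expect_equal(back$draws, fit$draws, tolerance = 1e-12,
               ignore_attr = FALSE)
  expect_equal(back$prior$sigma_focal, 0.068)
  expect_equal(back$centers, fit$centers)
  expect_equal(back$basis_coef, fit$basis_coef)
})
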