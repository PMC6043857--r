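#' Trajectory profile for model-implied curves
#'
#' Describes the person profile at which model-implied trajectories are
#' evaluated.  The default mirrors the conventional display: a man born in
#' 1935, first sample, education 3 years below, at, and 3 years above the
#' education center, across ages 35--85.
#'
#' @param birth_year calendar birth year.
#' @param sex 0 male / 1 female.
#' @param sample_code 0/1 sample code.
#' @param education_offsets years of education relative to the education
#'   center.
#' @param age_range `c(min, max)` ages (years) for the grid.
#' @param age_step grid step in years.
#' @return object of class `trajectory_profile`.
#' @export
trajectory_profile <- function(birth_year = 1935, sex = 0, sample_code = 0,
                               education_offsets = c(-3, 0, 3),
                               age_range = c(35, 85), age_step = 1) {
  structure(list(birth_year = birth_year, sex = sex,
                 sample_code = sample_code,
                 education_offsets = education_offsets,
                 age_range = age_range, age_step = age_step),
            class = "trajectory_profile")
}

# Design row(s) for a profile on an age grid, using the centers and
# quadratic-basis projection coefficients of a fitted/prepared dataset.
profile_design <- function(profile, centers, basis_coef, ages) {
  age_c <- ages - centers[["age"]]
  lin <- age_c
  quad <- age_c^2 - basis_coef[["c0"]] - basis_coef[["c1"]] * age_c
  cohort_c <- profile$birth_year - centers[["cohort"]]
  function(offset) {
    build_design(age_lin = lin, age_quad = quad,
                 cohort_c = rep(cohort_c, length(ages)),
                 edu_c = rep(offset, length(ages)),
                 sex = rep(profile$sex, length(ages)),
                 sample_code = rep(profile$sample_code, length(ages)))
  }
}

#' Model-implied growth trajectories
#'
#' Evaluates the fixed-effects linear predictor (random effects at zero)
#' over an age grid for each education offset in the profile, using the
#' covariate centers and quadratic-basis coefficients recorded with the
#' data the model was fitted to.
#'
#' @param gamma named vector of the 25 fixed effects, or a `growth_fit`
#'   (whose pooled posterior-mean coefficients and recorded basis are used).
#' @param profile a [trajectory_profile()].
#' @param centers,basis_coef covariate centers and quadratic projection
#'   coefficients; taken from the fit when `gamma` is a `growth_fit`.
#' @return `data.frame` with columns `age`, `education_offset`, `predicted`.
#' @export
implied_trajectories <- function(gamma, profile = trajectory_profile(),
                                 centers = NULL, basis_coef = NULL) {
  if (inherits(gamma, "growth_fit")) {
    centers <- centers %||% gamma$centers
    basis_coef <- basis_coef %||% gamma$basis_coef
    gamma <- colMeans(apply(gamma$draws[, , design_colnames(), drop = FALSE],
                            3L, as.numeric))
  }
  if (is.null(centers) || is.null(basis_coef))
    stopf("'centers' and 'basis_coef' are required when 'gamma' is a plain vector")
  nm <- design_colnames()
  if (is.null(names(gamma)) || !setequal(names(gamma), nm))
    stopf("'gamma' must carry the 25 design-column names")
  gamma <- gamma[nm]
  ages <- seq(profile$age_range[1], profile$age_range[2],
              by = profile$age_step)
  mk <- profile_design(profile, centers, basis_coef, ages)
  out <- lapply(profile$education_offsets, function(e)
    data.frame(age = ages, education_offset = e,
               predicted = drop(mk(e) %*% gamma)))
  do.call(rbind, out)
}

#' Posterior contrasts of linear slopes between education offsets
#'
#' For each pair of education offsets in the profile, forms the per-draw
#' difference in the model-implied linear age slope at the profile's
#' covariates and summarizes it with MAP and 95% HDI.  Under parallel
#' trajectories (no education-by-slope effect) every contrast's HDI should
#' cover zero.
#'
#' @param fit a `growth_fit`.
#' @param profile a [trajectory_profile()].
#' @return `data.frame` with columns `offset_a`, `offset_b`, `map`,
#'   `hdi_lower`, `hdi_upper`, `contains_zero`.
#' @export
slope_difference_hdi <- function(fit, profile = trajectory_profile()) {
  stopifnot(inherits(fit, "growth_fit"))
  cohort_c <- profile$birth_year - fit$centers[["cohort"]]
  sx <- profile$sex
  # slope at offset e: LS + LS:C*c + LS:E*e + LS:S*s + LS:CE*c*e
  #                      + LS:CS*c*s + LS:ES*e*s + LS:CES*c*e*s
  slope_draws <- function(e) {
    pooled_draws(fit, "LS") +
      pooled_draws(fit, "LS x Cohort") * cohort_c +
      pooled_draws(fit, "LS x Education") * e +
      pooled_draws(fit, "LS x Sex") * sx +
      pooled_draws(fit, "LS x Cohort x Education") * cohort_c * e +
      pooled_draws(fit, "LS x Cohort x Sex") * cohort_c * sx +
      pooled_draws(fit, "LS x Education x Sex") * e * sx +
      pooled_draws(fit, "LS x Cohort x Education x Sex") * cohort_c * e * sx
  }
  offs <- profile$education_offsets
  pairs <- utils::combn(seq_along(offs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    jk <- pairs[, p]
    d <- slope_draws(offs[jk[1]]) - slope_draws(offs[jk[2]])
    h <- hdi(d)
    data.frame(offset_a = offs[jk[1]], offset_b = offs[jk[2]],
               map = map_estimate(d),
               hdi_lower = unname(h["lower"]), hdi_upper = unname(h["upper"]),
               contains_zero = h["lower"] <= 0 && h["upper"] >= 0)
  })
  do.call(rbind, rows)
}

#' Interval report for the cohort-by-education parameter
#'
#' Summarizes the exploratory cohort-moderation parameter (`Cohort x
#' Education`) per outcome by MAP and 95% HDI, flagging whether the
#' interval excludes zero.  A boundary exactly at zero counts as
#' inclusion.  No Bayes factor is computed for this parameter.
#'
#' @param fits named list of `growth_fit` objects (names are outcome
#'   labels) or of [summarize_fit()] data frames.
#' @return `data.frame` with columns `outcome`, `map`, `hdi_lower`,
#'   `hdi_upper`, `excludes_zero`.
#' @export
exploratory_gamma05_report <- function(fits) {
  rows <- lapply(names(fits), function(o) {
    f <- fits[[o]]
    s <- if (inherits(f, "growth_fit")) summarize_fit(f) else f
    r <- s[s$parameter == "Cohort x Education", , drop = FALSE]
    data.frame(outcome = o, map = r$map, hdi_lower = r$hdi_lower,
               hdi_upper = r$hdi_upper,
               excludes_zero = r$hdi_lower > 0 || r$hdi_upper < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run configuration for the end-to-end analysis
#'
#' @param input `"synthetic"` or the path to a long-format CSV.
#' @param outcomes outcome columns to analyze (subset of `va`, `sk`, `em`).
#' @param design a [study_design()] (used when `input = "synthetic"`).
#' @param truth named list of [true_parameters()] per outcome (synthetic).
#' @param prep a [prep_config()].
#' @param multipliers prior-width multipliers for the sensitivity grid.
#' @param base_estimates named vector of signed literature estimates per
#'   outcome (defaults to [default_base_estimate()] values).
#' @param chains,iter,warmup sampler settings.
#' @param seed integer master seed.
#' @param output_dir directory the report bundle is written to.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = "synthetic",
                       outcomes = c("va", "sk", "em"),
                       design = study_design(),
                       truth = default_truths(),
                       prep = prep_config(),
                       multipliers = c(1, 2, 4),
                       base_estimates = c(va = -0.002, sk = -0.004,
                                          em = -0.017),
                       chains = 4L, iter = 2000L, warmup = iter,
                       seed = 1L, output_dir = "results") {
  if (length(outcomes) == 0L) stopf("'outcomes' must be nonempty")
  if (is.null(seed)) stopf("'seed' is required")
  structure(list(input = input, outcomes = outcomes, design = design,
                 truth = truth, prep = prep, multipliers = multipliers,
                 base_estimates = base_estimates, chains = chains,
                 iter = iter, warmup = warmup, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a flat YAML run configuration
#'
#' Recognized keys mirror the [run_config()] arguments (`input`,
#' `outcomes`, `chains`, `iter`, `warmup`, `seed`, `output_dir`,
#' `multipliers`) plus flat design and preparation keys named after the
#' [study_design()] and [prep_config()] fields.  `seed` is required.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stopf("config must provide a 'seed' key")
  dn <- names(formals(study_design))
  pn <- names(formals(prep_config))
  design <- do.call(study_design, y[intersect(names(y), dn)])
  prep <- do.call(prep_config, y[intersect(names(y), pn)])
  args <- y[intersect(names(y), c("input", "outcomes", "multipliers",
                                  "chains", "iter", "warmup", "seed",
                                  "output_dir"))]
  args$design <- design
  args$prep <- prep
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> prepare -> fit -> hypothesis test for
#' each requested outcome and writes a report bundle to
#' `cfg$output_dir`: per outcome a summary CSV of MAP and 95% HDI for all
#' 29 parameters (`table1_<outcome>.csv`), a prior-sensitivity CSV
#' (`table2_<outcome>.csv`), model-implied trajectories
#' (`trajectories_<outcome>.csv`), plus a cohort-by-education report
#' (`gamma05.csv`) and a plain-text log of seeds, sampler settings and
#' per-parameter Rhat.
#'
#' @param cfg a [run_config()] or the path to a YAML config file.
#' @return (invisibly) a list per outcome with elements `prepared`, `fit`
#'   (reference fit), `summary`, `sensitivity`, `trajectories`, plus
#'   `gamma05` and the `paths` of all written files.  An error is raised if
#'   any reference fit fails the Rhat < 1.01 protocol.
#' @export
run_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  if (identical(cfg$input, "synthetic")) {
    data <- generate_cohort(cfg$design, cfg$truth, seed = cfg$seed,
                            centers = list(age = cfg$prep$age_center,
                                           cohort = cfg$prep$cohort_center,
                                           education = cfg$prep$education_center))
  } else {
    data <- read_cohort_csv(cfg$input)
  }

  log_lines <- c(sprintf("seed: %d", cfg$seed),
                 sprintf("sampler: %d chains x %d draws (warmup %d)",
                         cfg$chains, cfg$iter, cfg$warmup))
  out <- list(); paths <- character(0); fits <- list()
  set.seed(cfg$seed)
  outcome_seeds <- sample.int(.Machine$integer.max - 1L,
                              2L * length(cfg$outcomes))

  for (k in seq_along(cfg$outcomes)) {
    o <- cfg$outcomes[k]
    prepared <- prepare_dataset(data, o, cfg$prep)
    fit <- fit_growth(prepared, prior_spec(), chains = cfg$chains,
                      iter = cfg$iter, warmup = cfg$warmup,
                      seed = outcome_seeds[2L * k - 1L])
    summ <- summarize_fit(fit)
    p1 <- file.path(cfg$output_dir, paste0("table1_", o, ".csv"))
    utils::write.csv(summ, p1, row.names = FALSE)

    grid <- sensitivity_grid(cfg$base_estimates[[o]], cfg$multipliers)
    sens <- run_sensitivity(prepared, grid, chains = cfg$chains,
                            iter = cfg$iter, warmup = cfg$warmup,
                            seed = outcome_seeds[2L * k])
    p2 <- file.path(cfg$output_dir, paste0("table2_", o, ".csv"))
    utils::write.csv(sens$table, p2, row.names = FALSE)

    traj <- implied_trajectories(fit)
    p3 <- file.path(cfg$output_dir, paste0("trajectories_", o, ".csv"))
    utils::write.csv(traj, p3, row.names = FALSE)

    log_lines <- c(log_lines,
                   sprintf("[%s] n_persons=%d n_rows=%d fit_seed=%d max_rhat=%.4f",
                           o, fit$n_persons, fit$n_rows, fit$seed,
                           max(fit$rhat, na.rm = TRUE)),
                   sprintf("[%s] rhat: %s", o,
                           paste(sprintf("%s=%.4f", names(fit$rhat), fit$rhat),
                                 collapse = " ")),
                   sprintf("[%s] sensitivity max_rhat per fit: %s", o,
                           paste(sprintf("%.4f", sens$max_rhat), collapse = " ")))
    fits[[o]] <- fit
    paths <- c(paths, p1, p2, p3)
    out[[o]] <- list(prepared = prepared, fit = fit, summary = summ,
                     sensitivity = sens, trajectories = traj)
  }

  g5 <- exploratory_gamma05_report(fits)
  p5 <- file.path(cfg$output_dir, "gamma05.csv")
  utils::write.csv(g5, p5, row.names = FALSE)
  plog <- file.path(cfg$output_dir, "run_log.txt")
  writeLines(log_lines, plog)
  paths <- c(paths, p5, plog)

  not_conv <- names(fits)[!vapply(fits, `[[`, logical(1), "converged")]
  if (length(not_conv))
    stopf("convergence protocol failed (Rhat >= 1.01) for outcome(s): %s",
          paste(not_conv, collapse = ", "))
  invisible(c(out, list(gamma05 = g5, paths = paths)))
}
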