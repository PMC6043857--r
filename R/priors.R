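#' Prior specification for the growth model
#'
#' Weakly informative priors for all parameters: Normal(50, 20) on the
#' intercept, Normal(0, 3) on every other regression coefficient,
#' half-Cauchy(0, 10) on the three scale parameters (`sd_u0`, `sd_u1`,
#' `sd_resid`) and a flat LKJ(1) prior on the 2x2 random-effects
#' correlation.  When `sigma_focal` is set, the focal education-by-slope
#' coefficient instead gets a Normal(0, `sigma_focal`) prior, which is what
#' the Savage-Dickey Bayes factor conditions on.
#'
#' @param intercept_mean,intercept_sd Normal prior on the intercept.
#' @param coef_sd SD of the Normal(0, .) prior on non-focal coefficients.
#' @param scale_cauchy scale of the half-Cauchy prior on SD parameters.
#' @param lkj_eta LKJ shape; only 1 (flat on the correlation) is supported.
#' @param sigma_focal optional SD of the zero-centered Normal prior on the
#'   focal `LS x Education` coefficient; `NULL` means it shares `coef_sd`.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_mean = 50, intercept_sd = 20,
                       coef_sd = 3, scale_cauchy = 10, lkj_eta = 1,
                       sigma_focal = NULL) {
  for (v in c("intercept_sd", "coef_sd", "scale_cauchy")) {
    val <- get(v)
    assert_scalar_number(val, v)
    if (val <= 0) stopf("'%s' must be positive", v)
  }
  if (!identical(as.numeric(lkj_eta), 1))
    stopf("only the flat LKJ(1) correlation prior is supported")
  if (!is.null(sigma_focal)) {
    assert_scalar_number(sigma_focal, "sigma_focal")
    if (sigma_focal <= 0) stopf("'sigma_focal' must be positive")
  }
  structure(list(intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 coef_sd = coef_sd, scale_cauchy = scale_cauchy,
                 lkj_eta = 1, sigma_focal = sigma_focal),
            class = "prior_spec")
}

# Prior mean and SD vectors for the 25 fixed effects.
gamma_prior_mean <- function(prior) {
  m <- rep(0, 25)
  m[1L] <- prior$intercept_mean
  m
}

gamma_prior_sd <- function(prior) {
  s <- rep(prior$coef_sd, 25)
  s[1L] <- prior$intercept_sd
  if (!is.null(prior$sigma_focal)) s[focal_index()] <- prior$sigma_focal
  s
}

log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) + stats::dcauchy(x, 0, scale, log = TRUE), -Inf)
}

#' Joint log prior density
#'
#' Sum of the log prior densities of all 29 parameters under a
#' [prior_spec()]: Normals on the 25 fixed effects (with the focal prior on
#' `LS x Education` when set), half-Cauchy on the positive half-line for
#' the three SDs, and the flat LKJ(1) contribution `log(1/2)` for the
#' correlation.  Out-of-support values (an SD at or below zero, |rho| >= 1)
#' give `-Inf` rather than an error.
#'
#' @param params named numeric vector of length 29 (see [param_names()]) or
#'   a list with elements `gamma`, `sd_u0`, `sd_u1`, `rho`, `sd_resid`.
#' @param prior a [prior_spec()].
#' @return scalar log density.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  p <- as_param_list(params)
  if (p$sd_u0 <= 0 || p$sd_u1 <= 0 || p$sd_resid <= 0 || abs(p$rho) >= 1)
    return(-Inf)
  sum(stats::dnorm(p$gamma, gamma_prior_mean(prior), gamma_prior_sd(prior),
                   log = TRUE)) +
    log_half_cauchy(p$sd_u0, prior$scale_cauchy) +
    log_half_cauchy(p$sd_u1, prior$scale_cauchy) +
    log_half_cauchy(p$sd_resid, prior$scale_cauchy) +
    log(0.5)
}

# Accepts a named length-29 vector or a truth-style list and returns
# list(gamma, sd_u0, sd_u1, rho, sd_resid) with gamma in canonical order.
as_param_list <- function(params) {
  if (inherits(params, "true_parameters"))
    return(params[c("gamma", "sd_u0", "sd_u1", "rho", "sd_resid")])
  if (is.list(params)) {
    need <- c("gamma", "sd_u0", "sd_u1", "rho", "sd_resid")
    if (!all(need %in% names(params)))
      stopf("'params' list must carry gamma, sd_u0, sd_u1, rho, sd_resid")
    g <- params$gamma
    if (length(g) != 25L) stopf("'gamma' must have length 25")
    if (!is.null(names(g)) && setequal(names(g), design_colnames()))
      g <- g[design_colnames()]
    return(list(gamma = as.numeric(g), sd_u0 = params$sd_u0,
                sd_u1 = params$sd_u1, rho = params$rho,
                sd_resid = params$sd_resid))
  }
  if (is.numeric(params) && length(params) == 29L) {
    if (!is.null(names(params)) && setequal(names(params), param_names()))
      params <- params[param_names()]
    return(list(gamma = as.numeric(params[1:25]),
                sd_u0 = unname(params[26]), sd_u1 = unname(params[27]),
                rho = unname(params[28]), sd_resid = unname(params[29])))
  }
  stopf("'params' must be a named length-29 vector or a parameter list")
}
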