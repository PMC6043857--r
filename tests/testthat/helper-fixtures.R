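# Shared fixtures: small designs, truths and oracles used across test files.

# Compact two-sample design whose cohorts all survive the default exclusion
# bands, with exact cell bookkeeping (8 cohorts x 2 samples x n per cell).
small_design <- function(persons_per_cell = 10L, dropout_hazard = 0,
                         cohorts = seq(1919, 1954, by = 5)) {
  study_design(cohort_birth_years = cohorts,
               persons_per_cell = persons_per_cell,
               dropout_hazard = dropout_hazard,
               education_min = 6, education_max = 25)
}

# Prep settings matched to synthetic data that is already on the T scale
# and should be retained in full (no exclusions, paper centers).
synthetic_prep <- function() {
  prep_config(standardize = FALSE, excluded_cohorts = list(),
              education_min_allowed = 0)
}

# A truth with a single nonzero coefficient (plus intercept), handy for
# isolating one effect.
sparse_truth <- function(..., sd_u0 = 0, sd_u1 = 0, rho = 0, sd_resid = 0) {
  g <- stats::setNames(rep(0, 25), design_colnames())
  vals <- list(...)
  for (nm in names(vals)) g[nm] <- vals[[nm]]
  true_parameters(g, sd_u0 = sd_u0, sd_u1 = sd_u1, rho = rho,
                  sd_resid = sd_resid)
}

# Independent oracle: marginal log likelihood by adaptive 2-D Gauss-Hermite
# quadrature over the person random effects (u0, u1).  The grid is centered
# at each person's numerically located integrand mode and scaled by the
# numerical Hessian, so the quadrature converges fast even when a person's
# random-effect posterior sits far from the prior mean.
gh_loglik <- function(params, prepared, n_nodes = 30) {
  p <- cogdecline:::as_param_list(params)
  gh <- pracma::gaussHermite(n_nodes)
  Su <- matrix(c(p$sd_u0^2, p$sd_u0 * p$sd_u1 * p$rho,
                 p$sd_u0 * p$sd_u1 * p$rho, p$sd_u1^2), 2)
  Sinv <- solve(Su)
  ldSu <- determinant(Su)$modulus
  mu <- drop(prepared$X %*% p$gamma)
  ll <- 0
  for (idx in split(seq_len(nrow(prepared$data)), prepared$person)) {
    ages <- prepared$data$age_lin[idx]
    y <- prepared$data$y[idx]
    h <- function(u) {
      sum(stats::dnorm(y, mu[idx] + u[1] + u[2] * ages, p$sd_resid,
                       log = TRUE)) -
        0.5 * drop(t(u) %*% Sinv %*% u) - log(2 * pi) - 0.5 * ldSu
    }
    opt <- stats::optim(c(0, 0), function(u) -h(u), method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    H <- stats::optimHess(opt$par, function(u) -h(u))
    L <- t(chol(solve(H)))
    li <- 0
    for (j in seq_len(n_nodes)) {
      for (k in seq_len(n_nodes)) {
        z <- c(gh$x[j], gh$x[k])
        u <- opt$par + sqrt(2) * drop(L %*% z)
        li <- li + gh$w[j] * gh$w[k] * exp(h(u) + sum(z^2))
      }
    }
    ll <- ll + log(2 * abs(det(L)) * li)
  }
  ll
}

# Relative Monte Carlo standard error of the Gaussian-KDE density at zero,
# by block resampling of the pooled draws (blocks of contiguous iterations,
# respecting what little autocorrelation the draws carry).
kde_zero_rel_se <- function(draws, blocks = 10) {
  bw <- stats::bw.nrd0(draws)
  f <- mean(stats::dnorm(0, draws, bw))
  idx <- cut(seq_along(draws), blocks, labels = FALSE)
  fs <- vapply(split(draws, idx),
               function(d) mean(stats::dnorm(0, d, bw)), numeric(1))
  stats::sd(fs) / sqrt(blocks) / f
}

# Random-walk Metropolis draws for the conjugate normal-mean model
# y_i ~ Normal(theta, 1), theta ~ Normal(0, prior_sd), given sufficient
# statistics (n, ybar).  Used as the sampling front-end for the conjugate
# Savage-Dickey oracle check.  The density ratio is evaluated 2.4 posterior
# SDs into the tail, so a large effective sample size is needed; burn-in is
# discarded.
conjugate_mh_draws <- function(n, ybar, prior_sd = 1, n_iter = 50000,
                               chains = 4, seed = 1, burn = 1000) {
  lp <- function(th) -n * (th - ybar)^2 / 2 +
    stats::dnorm(th, 0, prior_sd, log = TRUE)
  set.seed(seed)
  unlist(lapply(seq_len(chains), function(ch) {
    th <- stats::rnorm(1, 0, prior_sd)
    cur <- lp(th)
    out <- numeric(n_iter + burn)
    for (t in seq_along(out)) {
      prop <- th + stats::rnorm(1, 0, 0.5)
      lpp <- lp(prop)
      if (log(stats::runif(1)) < lpp - cur) { th <- prop; cur <- lpp }
      out[t] <- th
    }
    out[-seq_len(burn)]
  }))
}
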