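#' Fit the hierarchical growth model by MCMC
#'
#' Samples from the posterior proportional to
#' `exp(log_likelihood + log_prior)` using a blocked sampler: the 25 fixed
#' effects are drawn exactly from their Gaussian full conditional (the
#' marginalized likelihood is Gaussian in the coefficients, and their
#' priors are Normal), and the four variance-structure parameters are
#' updated by univariate slice sampling (stepping out and shrinkage) on the
#' unconstrained scale (`log` for the SDs, `atanh` for the correlation)
#' with the appropriate Jacobian terms.  Slice widths are tuned during
#' warmup from the chain's own spread and frozen afterwards, so the
#' retained draws target the exact posterior.
#'
#' @param prepared a [prepare_dataset()] result; a zero-row dataset is
#'   allowed, in which case the posterior equals the prior.
#' @param prior a [prior_spec()].
#' @param chains number of chains (default 4).
#' @param iter post-warmup draws per chain (default 2000).
#' @param warmup warmup iterations per chain (default: equal to `iter`).
#' @param seed integer seed; per-chain seeds are derived from it.
#' @param v_sweeps slice-sampling sweeps over the four variance parameters
#'   per iteration (extra sweeps improve mixing of the weakly identified
#'   slope SD and correlation at modest cost).
#' @return object of class `growth_fit`: draws array
#'   `[iter, chain, parameter]` with the 29 parameters of [param_names()],
#'   plus metadata (`prior`, `seed`, `rhat`, `converged`, slice-sampler
#'   evaluation counts, outcome label, person/row counts, covariate
#'   centers and quadratic-basis coefficients of the fitted data).
#' @export
fit_growth <- function(prepared, prior = prior_spec(), chains = 4L,
                       iter = 2000L, warmup = iter, seed = 1L,
                       v_sweeps = 2L) {
  stopifnot(inherits(prior, "prior_spec"))
  if (chains < 1L || iter < 2L) stopf("need chains >= 1 and iter >= 2")
  empty <- is.null(prepared) || nrow(prepared$data) == 0L
  ss <- if (empty) NULL else suff_stats(prepared)
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  sdy <- if (empty) 1 else max(stats::sd(prepared$data$y), 1e-3)
  nsw <- max(1L, as.integer(v_sweeps))
  draws <- array(NA_real_, dim = c(iter, chains, 29L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 param_names()))
  evals <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    # overdispersed starts for the variance parameters (gamma is drawn
    # exactly from its full conditional, so its start is irrelevant)
    z <- c(log(0.7 * sdy) + stats::runif(1, -1, 1),
           log(0.05 * sdy) + stats::runif(1, -1.5, 1.5),
           atanh(stats::runif(1, -0.5, 0.5)),
           log(0.7 * sdy) + stats::runif(1, -1, 1))
    gamma <- rep(0, 25)
    width <- rep(1, 4)
    zm <- z; zv <- rep(0.25, 4); nadapt <- 0
    n_evals <- 0

    target_z <- function(z, rs) {
      v <- c(exp(z[1]), exp(z[2]), tanh(z[3]), exp(z[4]))
      ll <- if (empty) 0 else
        profile_loglik(ss, rs$rss, rs$d1, rs$d2, v[1], v[2], v[3], v[4])
      if (!is.finite(ll)) return(-Inf)
      lp <- log_half_cauchy(v[1], prior$scale_cauchy) +
        log_half_cauchy(v[2], prior$scale_cauchy) +
        log_half_cauchy(v[4], prior$scale_cauchy) + log(0.5)
      jac <- z[1] + z[2] + z[4] + log1p(-v[3]^2)
      ll + lp + jac
    }

    total <- warmup + iter
    for (t in seq_len(total)) {
      v <- c(exp(z[1]), exp(z[2]), tanh(z[3]), exp(z[4]))
      gamma <- draw_gamma(ss, v[1], v[2], v[3], v[4], prior)
      rs <- if (empty) NULL else residual_stats(ss, gamma)
      lp_z <- target_z(z, rs)

      # slice-sample each unconstrained variance coordinate
      for (s in seq_len(nsw)) {
        for (j in 1:4) {
          tg <- function(x) { zj <- z; zj[j] <- x; target_z(zj, rs) }
          y0 <- lp_z - stats::rexp(1)
          w <- width[j]
          L <- z[j] - w * stats::runif(1)
          R <- L + w
          steps <- 0L
          while (steps < 30L && tg(L) > y0) { L <- L - w; steps <- steps + 1L }
          steps <- 0L
          while (steps < 30L && tg(R) > y0) { R <- R + w; steps <- steps + 1L }
          repeat {
            x1 <- stats::runif(1, L, R)
            lp1 <- tg(x1)
            n_evals <- n_evals + 1
            if (lp1 >= y0) { z[j] <- x1; lp_z <- lp1; break }
            if (x1 < z[j]) L <- x1 else R <- x1
            if (R - L < 1e-12) { lp_z <- tg(z[j]); break }
          }
        }
      }
      if (t <= warmup) {
        # slice widths from a running spread estimate, frozen after warmup
        nadapt <- nadapt + 1
        dzm <- z - zm
        zm <- zm + dzm / (nadapt + 10)
        zv <- zv + (dzm * (z - zm) - zv) / (nadapt + 10)
        width <- pmin(pmax(3 * sqrt(pmax(zv, 1e-8)), 0.05), 10)
      }

      if (t > warmup) {
        v <- c(exp(z[1]), exp(z[2]), tanh(z[3]), exp(z[4]))
        draws[t - warmup, ch, ] <- c(gamma, v[1], v[2], v[3], v[4])
      }
    }
    evals[ch] <- n_evals / total
  }

  rh <- apply(draws, 3L, function(m) split_rhat(m))
  converged <- all(rh < 1.01, na.rm = TRUE)
  if (!converged)
    warning(sprintf("chains may not have converged: max Rhat = %.4f (%s)",
                    max(rh, na.rm = TRUE), names(which.max(rh))),
            call. = FALSE)
  structure(list(
    draws = draws, prior = prior, seed = as.integer(seed),
    chains = chains, iter = iter, warmup = warmup,
    rhat = rh, converged = converged, slice_evals = evals,
    outcome = if (empty) NA_character_ else prepared$outcome,
    n_persons = if (empty) 0L else length(prepared$person_ids),
    n_rows = if (empty) 0L else nrow(prepared$data),
    centers = if (empty) NULL else prepared$centers,
    basis_coef = if (empty) NULL else prepared$basis_coef
  ), class = "growth_fit")
}

# Split-chain potential scale reduction for one parameter; m is an
# iter x chain matrix.
split_rhat <- function(m) {
  iter <- nrow(m)
  half <- floor(iter / 2)
  if (half < 2L) stopf("need at least 4 iterations per chain")
  parts <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(iter - half + 1):iter, , drop = FALSE])
  if (ncol(parts) < 2L) stopf("need at least 2 chains (after splitting)")
  cm <- colMeans(parts)
  cv <- apply(parts, 2L, stats::var)
  W <- mean(cv)
  B <- half * stats::var(cm)
  if (!is.finite(W) || W == 0) {
    return(if (!is.finite(B) || B == 0) 1.0 else Inf)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Split-chain Gelman--Rubin diagnostic
#'
#' Computes the split-chain potential scale reduction factor per parameter:
#' each chain is halved, and the ratio of pooled to within-(half-)chain
#' variance is formed.  Values near 1 indicate mixing; the conventional
#' convergence cutoff is 1.01.  Degenerate inputs with zero total variance
#' return exactly 1.
#'
#' @param x a `growth_fit`, or an `iter x chain` matrix of draws for a
#'   single parameter (at least 2 chains and 4 iterations).
#' @return named numeric vector (or scalar for a matrix input).
#' @export
rhat <- function(x) {
  if (inherits(x, "growth_fit")) return(x$rhat)
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stopf("need at least 2 chains")
    return(split_rhat(x))
  }
  stopf("'x' must be a growth_fit or an iter x chain matrix")
}

#' Pool posterior draws of one parameter across chains
#'
#' @param fit a `growth_fit`.
#' @param parameter parameter name (see [param_names()]).
#' @return numeric vector of `iter * chains` pooled draws.
#' @export
pooled_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!parameter %in% dimnames(fit$draws)[[3]])
    stopf("unknown parameter '%s'", parameter)
  as.numeric(fit$draws[, , parameter])
}

#' Posterior summary: MAP, mean, HDI and Rhat per parameter
#'
#' MAP is the mode of a Gaussian-kernel density estimate of each pooled
#' marginal ([map_estimate()]); the HDI is the shortest interval containing
#' `hdi_mass` of the pooled draws ([hdi()]).
#'
#' @param fit a `growth_fit`.
#' @param hdi_mass HDI probability mass, in (0, 1).
#' @return `data.frame` with columns `parameter`, `map`, `mean`,
#'   `hdi_lower`, `hdi_upper`, `rhat`.
#' @export
summarize_fit <- function(fit, hdi_mass = 0.95) {
  stopifnot(inherits(fit, "growth_fit"))
  nm <- dimnames(fit$draws)[[3]]
  rows <- lapply(nm, function(p) {
    x <- as.numeric(fit$draws[, , p])
    h <- hdi(x, hdi_mass)
    data.frame(parameter = p, map = map_estimate(x), mean = mean(x),
               hdi_lower = unname(h["lower"]), hdi_upper = unname(h["upper"]),
               rhat = unname(fit$rhat[p]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth-model fit: %d chains x %d draws (warmup %d), outcome '%s'\n",
              x$chains, x$iter, x$warmup, x$outcome))
  cat(sprintf("  %d persons, %d rows; max Rhat %.4f (%s)\n",
              x$n_persons, x$n_rows, max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$prior$sigma_focal))
    cat(sprintf("  focal prior: Normal(0, %g) on '%s'\n",
                x$prior$sigma_focal, design_colnames()[focal_index()]))
  invisible(x)
}

#' Persist posterior draws and metadata
#'
#' Writes a draws CSV (`chain`, `iteration`, one column per parameter) and
#' a JSON metadata sidecar (seed, sampler settings, prior, Rhat values).
#'
#' @param fit a `growth_fit`.
#' @param path CSV path for the draws.
#' @param meta_path optional JSON path (default: `path` with `.json`).
#' @export
write_draws_csv <- function(fit, path, meta_path = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  nm <- dimnames(fit$draws)[[3]]
  tab <- do.call(rbind, lapply(seq_len(fit$chains), function(ch) {
    d <- as.data.frame(fit$draws[, ch, ])
    names(d) <- nm
    cbind(chain = ch, iteration = seq_len(fit$iter), d)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  meta_path <- meta_path %||% sub("\\.csv$", ".json", path)
  meta <- list(seed = fit$seed, chains = fit$chains, iter = fit$iter,
               warmup = fit$warmup, outcome = fit$outcome,
               prior = unclass(fit$prior), rhat = as.list(fit$rhat),
               converged = fit$converged,
               n_persons = fit$n_persons, n_rows = fit$n_rows,
               centers = as.list(fit$centers),
               basis_coef = as.list(fit$basis_coef))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a fit from a draws CSV and its metadata sidecar
#'
#' Rebuilds a `growth_fit` from files written by [write_draws_csv()],
#' recomputing the split-chain Rhat from the stored draws.
#'
#' @param path draws CSV path.
#' @param meta_path JSON sidecar path (default: `path` with `.json`).
#' @return a `growth_fit`.
#' @export
read_draws_csv <- function(path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.csv$", ".json", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  nm <- param_names()
  chains <- length(unique(tab$chain))
  iter <- max(tab$iteration)
  draws <- array(NA_real_, dim = c(iter, chains, 29L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)), nm))
  for (ch in seq_len(chains))
    draws[, ch, ] <- as.matrix(tab[tab$chain == ch, nm])
  rh <- apply(draws, 3L, split_rhat)
  prior <- do.call(prior_spec, as.list(meta$prior))
  structure(list(
    draws = draws, prior = prior, seed = meta$seed, chains = chains,
    iter = iter, warmup = meta$warmup, rhat = rh,
    converged = all(rh < 1.01, na.rm = TRUE), slice_evals = NA_real_,
    outcome = meta$outcome, n_persons = meta$n_persons %||% NA_integer_,
    n_rows = meta$n_rows %||% NA_integer_,
    centers = unlist(meta$centers), basis_coef = unlist(meta$basis_coef)
  ), class = "growth_fit")
}
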