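#' Marginal log likelihood of the growth model
#'
#' Computes the likelihood with the person-level random effects integrated
#' out analytically: for person `i` with observed rows, the outcomes are
#' jointly Normal with mean `X_i gamma` and covariance
#' `Z_i Sigma_u Z_i' + sd_resid^2 I`, where `Z_i` has columns
#' `(1, age_lin)` and `Sigma_u` is built from `(sd_u0, sd_u1, rho)`.  The
#' quadratic slope has no random component.  Rows with a missing outcome
#' were already dropped during preparation.
#'
#' @param params named length-29 vector or parameter list (see
#'   [log_prior()]).
#' @param prepared a [prepare_dataset()] result (may have zero rows).
#' @return scalar log density.
#' @export
log_likelihood <- function(params, prepared) {
  p <- as_param_list(params)
  if (p$sd_resid <= 0) stopf("'sd_resid' must be positive")
  if (p$sd_u0 < 0 || p$sd_u1 < 0) stopf("random-effect SDs must be non-negative")
  if (abs(p$rho) > 1) stopf("'rho' must lie in [-1, 1]")
  n <- nrow(prepared$data)
  if (n == 0L) return(0)
  Su <- matrix(c(p$sd_u0^2, p$sd_u0 * p$sd_u1 * p$rho,
                 p$sd_u0 * p$sd_u1 * p$rho, p$sd_u1^2), 2L)
  r <- prepared$data$y - drop(prepared$X %*% p$gamma)
  ll <- 0
  for (idx in split(seq_len(n), prepared$person)) {
    Zi <- cbind(1, prepared$data$age_lin[idx])
    Vi <- Zi %*% Su %*% t(Zi) + diag(p$sd_resid^2, length(idx))
    R <- tryCatch(chol(Vi), error = function(e)
      stopf("implied covariance not positive definite for a person block (sd_u0=%g, sd_u1=%g, rho=%g, sd_resid=%g)",
            p$sd_u0, p$sd_u1, p$rho, p$sd_resid))
    z <- backsolve(R, r[idx], transpose = TRUE)
    ll <- ll - 0.5 * length(idx) * log(2 * pi) - sum(log(diag(R))) -
      0.5 * sum(z^2)
  }
  ll
}

# ---- fast vectorized machinery used by the sampler ------------------------
#
# Per-person sufficient statistics let both the marginal log likelihood and
# the Gaussian full conditional of the fixed effects be computed without
# per-person loops, via the Woodbury identity with 2x2 blocks:
#   V_i^{-1} = s^-2 I - s^-4 Z_i A_i^{-1} Z_i',  A_i = Su^{-1} + s^-2 Z_i'Z_i
#   A_i^{-1} = M_i^{-1} Su,                      M_i = I + s^-2 Su Z_i'Z_i
#   log det V_i = n_i log s^2 + log det M_i
# All M_i entries are scalar functions of (n_i, sum age, sum age^2).

suff_stats <- function(prepared) {
  d <- prepared$data
  pid <- prepared$person
  a <- d$age_lin
  y <- d$y
  X <- prepared$X
  list(
    pid = pid,
    n_i = as.numeric(tabulate(pid)),
    s1 = as.numeric(rowsum(a, pid)),
    s2 = as.numeric(rowsum(a^2, pid)),
    age = a, y = y, X = X,
    XtX = crossprod(X),
    Xty = drop(crossprod(X, y)),
    B1 = rowsum(X, pid),
    B2 = rowsum(X * a, pid),
    c1 = as.numeric(rowsum(y, pid)),
    c2 = as.numeric(rowsum(y * a, pid))
  )
}

# 2x2 blocks shared by the likelihood and the gamma conditional:
# returns det(M_i) and the symmetric entries of A_i^{-1} = adj(M_i) Su / det.
woodbury_blocks <- function(ss, su0, su1, rho, sig) {
  s00 <- su0^2; s01 <- su0 * su1 * rho; s11 <- su1^2
  is2 <- 1 / sig^2
  M11 <- 1 + is2 * (s00 * ss$n_i + s01 * ss$s1)
  M12 <- is2 * (s00 * ss$s1 + s01 * ss$s2)
  M21 <- is2 * (s01 * ss$n_i + s11 * ss$s1)
  M22 <- 1 + is2 * (s01 * ss$s1 + s11 * ss$s2)
  detM <- M11 * M22 - M12 * M21
  # A^{-1} = adj(M) Su / detM (symmetric up to roundoff; symmetrized)
  E11 <- M22 * s00 - M12 * s01
  E12 <- M22 * s01 - M12 * s11
  E21 <- -M21 * s00 + M11 * s01
  E22 <- -M21 * s01 + M11 * s11
  list(detM = detM, a11 = E11 / detM, a22 = E22 / detM,
       a12 = (E12 + E21) / (2 * detM))
}

# Marginal log likelihood given residual per-person stats (rss, d1, d2)
# where d = Z_i' r_i, at variance parameters v = c(su0, su1, rho, sig).
profile_loglik <- function(ss, rss, d1, d2, su0, su1, rho, sig) {
  wb <- woodbury_blocks(ss, su0, su1, rho, sig)
  if (any(wb$detM <= 0) || !all(is.finite(wb$detM))) return(-Inf)
  is2 <- 1 / sig^2
  quad <- rss * is2 - is2^2 *
    (wb$a11 * d1^2 + 2 * wb$a12 * d1 * d2 + wb$a22 * d2^2)
  ll <- -0.5 * sum(ss$n_i * (log(2 * pi) + log(sig^2)) + log(wb$detM) + quad)
  if (!is.finite(ll)) return(-Inf)
  ll
}

residual_stats <- function(ss, gamma) {
  r <- ss$y - drop(ss$X %*% gamma)
  list(rss = as.numeric(rowsum(r^2, ss$pid)),
       d1 = as.numeric(rowsum(r, ss$pid)),
       d2 = as.numeric(rowsum(r * ss$age, ss$pid)))
}

# Gaussian full conditional of gamma given variance parameters:
# precision P = X'V^{-1}X + P0, mean solve(P, X'V^{-1}y + P0 m0).
draw_gamma <- function(ss, su0, su1, rho, sig, prior) {
  sd0 <- gamma_prior_sd(prior)
  P0 <- 1 / sd0^2
  m0 <- gamma_prior_mean(prior)
  if (is.null(ss)) {                      # no data: sample from the prior
    return(stats::rnorm(25, m0, sd0))
  }
  wb <- woodbury_blocks(ss, su0, su1, rho, sig)
  is2 <- 1 / sig^2
  S <- crossprod(ss$B1, wb$a11 * ss$B1) +
    crossprod(ss$B1, wb$a12 * ss$B2) +
    crossprod(ss$B2, wb$a12 * ss$B1) +
    crossprod(ss$B2, wb$a22 * ss$B2)
  P <- is2 * ss$XtX - is2^2 * S
  m <- is2 * ss$Xty - is2^2 *
    (drop(crossprod(ss$B1, wb$a11 * ss$c1 + wb$a12 * ss$c2)) +
       drop(crossprod(ss$B2, wb$a12 * ss$c1 + wb$a22 * ss$c2)))
  P <- P + diag(P0, 25L)
  P <- (P + t(P)) / 2
  m <- m + P0 * m0
  R <- chol(P)
  mu <- backsolve(R, backsolve(R, m, transpose = TRUE))
  drop(mu + backsolve(R, stats::rnorm(25)))
}
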