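`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}

# Population SD (divide by n).  Used for T-standardization so that the
# first-occasion SD of the standardized scores is exactly t_sd.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Shortest interval containing a given posterior mass
#'
#' Computes the highest density interval (HDI) of a sample as the shortest
#' contiguous interval among the sorted draws that contains `mass` of them.
#' For unimodal marginals this matches the density-based HDI up to Monte
#' Carlo error.
#'
#' @param x numeric vector of draws.
#' @param mass probability mass the interval must contain, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) ||
      mass <= 0 || mass >= 1)
    stopf("'mass' must lie strictly between 0 and 1")
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stopf("no non-missing draws supplied")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Posterior mode from draws via kernel density estimation
#'
#' The marginal MAP estimate is taken as the maximizer of a Gaussian kernel
#' density estimate (Silverman's rule-of-thumb bandwidth) evaluated on a
#' 512-point grid spanning the range of the draws.
#'
#' @param x numeric vector of draws.
#' @return scalar mode estimate.
#' @export
map_estimate <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stopf("no non-missing draws supplied")
  if (diff(range(x)) == 0) return(x[1L])
  d <- stats::density(x, bw = "nrd0", n = 512L, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}
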