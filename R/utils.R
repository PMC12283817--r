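#' Round half up
#'
#' Commercial rounding (0.5 always rounds away from zero), used at monetary
#' and count reporting boundaries. `base::round()` rounds half to even, which
#' does not reproduce published penny-rounded totals such as 54.688 -> 54.69.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials (must be >= 1).
#' @param conf confidence level, default 0.95.
#' @return list with `estimate`, `se`, `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("cannot estimate a proportion from n = 0 observations")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(
    estimate = p,
    se = sqrt(p * (1 - p) / n),
    lower = min(p, max(0, centre - half)),
    upper = max(p, min(1, centre + half))
  )
}

#' Method-of-moments beta shape parameters
#'
#' Converts a (mean, se) pair for a quantity on (0, 1) into the shape
#' parameters of the beta distribution with those first two moments.
#'
#' @param mean mean, strictly inside (0, 1).
#' @param se standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @return list with `shape1` (alpha) and `shape2` (beta).
#' @export
beta_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("beta mean must lie strictly inside (0, 1)")
  if (se <= 0) stop("se must be positive")
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf("se = %g too large for a beta distribution with mean %g", se, mean))
  }
  nu <- mean * (1 - mean) / v - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# An uncertain quantity: point value plus an uncertainty descriptor used by
# the PSA. `se` may be given directly or recovered from a 95% CI as width/3.92.
unc <- function(mean, se = NULL, ci = NULL, dist = c("beta", "fixed")) {
  dist <- match.arg(dist)
  if (is.null(se) && !is.null(ci)) se <- (ci[2] - ci[1]) / 3.92
  if (is.null(se)) se <- 0
  structure(list(mean = mean, se = se, ci = ci, dist = dist), class = "adc_unc")
}

unc_mean <- function(x) if (inherits(x, "adc_unc")) x$mean else x

# Draw n values from an uncertain quantity (beta by method of moments;
# fixed quantities and zero-SE quantities return their mean).
unc_draw <- function(x, n) {
  if (!inherits(x, "adc_unc")) return(rep(x, n))
  if (x$dist == "fixed" || x$se == 0) return(rep(x$mean, n))
  sh <- beta_from_moments(x$mean, x$se)
  stats::rbeta(n, sh$shape1, sh$shape2)
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single proportion in [0, 1]", name))
  }
  invisible(x)
}
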