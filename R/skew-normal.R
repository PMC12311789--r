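## Skew-normal density, sampling and moment conversions.
##
## The bimodal distribution of mutant growth rates is modelled as a mixture
## of two skew-normal components. The density with location xi, scale omega
## and shape alpha is 2/omega * phi(z) * Phi(alpha z), z = (x - xi)/omega.
## Moments: delta = alpha/sqrt(1 + alpha^2),
##   mean = xi + omega * delta * sqrt(2/pi),
##   sd   = omega * sqrt(1 - 2 delta^2 / pi).

#' Skew-normal density
#'
#' @param x numeric vector of quantiles.
#' @param xi location parameter.
#' @param omega scale parameter (> 0).
#' @param alpha shape (skewness) parameter; 0 gives the normal density.
#' @return Density values.
#' @export
dskewnorm <- function(x, xi, omega, alpha) {
  if (omega <= 0) stop("omega must be > 0")
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

#' Sample from a skew-normal distribution
#'
#' Uses the standard construction from a pair of independent normals:
#' Z = delta |U0| + sqrt(1 - delta^2) U1 is skew-normal with shape alpha.
#'
#' @param n number of draws.
#' @inheritParams dskewnorm
#' @return Numeric vector of draws.
#' @export
rskewnorm <- function(n, xi, omega, alpha) {
  if (omega <= 0) stop("omega must be > 0")
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' Skew-normal distribution mean
#' @inheritParams dskewnorm
#' @return The distribution mean.
#' @export
skewnorm_mean <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * delta * sqrt(2 / pi)
}

#' Skew-normal distribution standard deviation
#' @inheritParams dskewnorm
#' @return The distribution standard deviation.
#' @export
skewnorm_sd <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  omega * sqrt(1 - 2 * delta^2 / pi)
}

#' Convert target moments to skew-normal (xi, omega) parameters
#'
#' Given a desired distribution mean and standard deviation and a shape
#' alpha, returns the location and scale yielding those moments. Used by the
#' synthetic landscape generator so component parameters can be specified on
#' the interpretable moment scale.
#'
#' @param mean,sd target distribution mean and standard deviation.
#' @param alpha shape parameter.
#' @return List with elements \code{xi}, \code{omega}, \code{alpha}.
#' @export
skewnorm_from_moments <- function(mean, sd, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  xi <- mean - omega * delta * sqrt(2 / pi)
  list(xi = xi, omega = omega, alpha = alpha)
}
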