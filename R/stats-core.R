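#' Standard-normal density at a quantile, with vanishing tails
#'
#' Evaluates phi(Phi^-1(x)) for probabilities `x`, defining the value at the
#' endpoints 0 and 1 as exactly 0 (the limit), so that tail terms drop out of
#' truncated-moment formulae instead of producing infinities.
#'
#' @param x Numeric vector of probabilities in \[0, 1\].
#' @return Numeric vector, phi(Phi^-1(x)) with 0 at x = 0 and x = 1.
#' @keywords internal
phi_at <- function(x) {
  stopifnot(is.numeric(x), all(x >= -1e-12 & x <= 1 + 1e-12))
  out <- numeric(length(x))
  inner <- x > 0 & x < 1
  out[inner] <- stats::dnorm(stats::qnorm(x[inner]))
  out
}

check_interval <- function(u, v, tol = 1e-12) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == 1L, length(v) == 1L)
  if (u < -tol || v > 1 + tol) {
    stop("quantile interval (", u, ", ", v, ") must lie within [0, 1]")
  }
  if (v - u <= tol) {
    stop("degenerate quantile interval: u = ", u, ", v = ", v,
         " encloses no probability mass")
  }
  invisible(TRUE)
}

#' Q factor of a quantile interval of the standard normal
#'
#' The dimensionless factor Q_{u,v} = \[phi(Phi^-1(v)) - phi(Phi^-1(u))\] / (v - u),
#' so that the mean of a normal with location `mu` and scale `sigma` truncated to
#' the quantile interval (u, v) is `mu - sigma * q_factor(u, v)`. Tail densities
#' at u = 0 or v = 1 are taken as 0. Antisymmetric under reflection of the
#' interval about 1/2: Q_{1-v,1-u} = -Q_{u,v}.
#'
#' @param u Lower probability, in \[0, 1).
#' @param v Upper probability, in (0, 1\]; must exceed `u`.
#' @return A single finite number.
#' @examples
#' q_factor(0.5, 1)  # -sqrt(2/pi)
#' q_factor(0, 1)    # 0
#' @export
q_factor <- function(u, v) {
  check_interval(u, v)
  (phi_at(v) - phi_at(u)) / (v - u)
}

#' Mean of a truncated normal distribution, parameterized by quantiles
#'
#' Mean of a N(mu, sigma^2) variable conditioned on lying between its own
#' u-quantile and v-quantile: mu_{u,v} = mu - sigma * Q_{u,v}. With (u, v) =
#' (p, 1) this is the population trimmed mean retained after trimming away the
#' lower fraction p; at p = 0.5 it equals mu + sigma * sqrt(2/pi).
#'
#' @param mu Location (outcome units).
#' @param sigma Scale, > 0 (outcome units).
#' @inheritParams q_factor
#' @return The truncated mean, in outcome units.
#' @examples
#' truncated_mean(0, 1, 0.5, 1)  # sqrt(2/pi)
#' truncated_mean(5, 2, 0, 1)    # 5, no truncation
#' @export
truncated_mean <- function(mu, sigma, u, v) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  mu - sigma * q_factor(u, v)
}

#' Second moment of a standard normal truncated to a quantile interval
#' @noRd
truncated_e2_std <- function(u, v) {
  check_interval(u, v)
  a <- if (u <= 0) 0 else stats::qnorm(u) * phi_at(u)
  b <- if (v >= 1) 0 else stats::qnorm(v) * phi_at(v)
  1 + (a - b) / (v - u)
}

#' Standard deviation of a truncated normal, parameterized by quantiles
#'
#' SD of a N(mu, sigma^2) variable conditioned on its quantile interval (u, v).
#' Used when inverting thinned-sample SDs back to full-sample SDs and when
#' checking the half-normal SD relation.
#'
#' @inheritParams truncated_mean
#' @return The truncated SD, in outcome units.
#' @export
truncated_sd <- function(sigma, u, v) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  m <- -q_factor(u, v)
  sigma * sqrt(truncated_e2_std(u, v) - m^2)
}

#' Half-normal SD factor and its inverse
#'
#' Under normality the retained half after 50% trimming is half-normal, with SD
#' sigma_t = sigma * sqrt(1 - 2/pi). The factor and its reciprocal convert
#' between a full-sample SD and the SD of its upper (or lower) half; the
#' reciprocal sqrt(pi/(pi - 2)) extrapolates a full-sample SD from an observed
#' 50%-trimmed fraction.
#'
#' @return A list with elements `factor` (sqrt(1 - 2/pi), about 0.60281) and
#'   `inverse` (sqrt(pi/(pi - 2)), about 1.65889).
#' @examples
#' half_normal_sd_factor()$factor * half_normal_sd_factor()$inverse  # 1
#' @export
half_normal_sd_factor <- function() {
  f <- sqrt(1 - 2 / pi)
  list(factor = f, inverse = 1 / f)
}
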