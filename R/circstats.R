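#' Wrap an angle to the signed interval (-180, 180]
#'
#' All signed angular differences in this package (response errors, relative
#' directions of the previous stimulus or response) live on (-180, 180], with
#' positive values denoting clockwise deviations. The tie at the half-turn is
#' resolved to +180 so that wrapping is deterministic.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each value in (-180, 180] and
#'   congruent to the input modulo 360.
#' @examples
#' wrap_signed(c(340, -180, 725))
#' @export
wrap_signed <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  out <- angle %% 360
  out[out > 180] <- out[out > 180] - 360
  # %% can return 0 for inputs like -180; convention maps the boundary to +180
  out[out == -180] <- 180
  out
}

#' Wrap an angle to the directional interval [0, 360)
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector in [0, 360).
#' @export
wrap_360 <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  angle %% 360
}

#' Signed circular distance between two directions
#'
#' Computes `a - b` on the circle, wrapped to (-180, 180]. Antisymmetric up to
#' the +180 boundary convention.
#'
#' @param a,b Numeric vectors of directions in degrees (recycled).
#' @return Signed differences in degrees.
#' @examples
#' circ_dist(10, 350) # 20, crossing 0
#' @export
circ_dist <- function(a, b) {
  wrap_signed(a - b)
}

#' Von Mises concentration equivalent to a Gaussian SD in degrees
#'
#' The convention tying degrees to concentration throughout the package:
#' a von Mises with concentration `kappa = 1/sd_rad^2` is locally analogous to
#' a Gaussian with standard deviation `sd` degrees (`sd_rad = sd * pi / 180`).
#' A 30-degree SD maps to kappa of about 3.65.
#'
#' @param sd Standard deviation in degrees, positive.
#' @return Concentration parameter (unitless).
#' @examples
#' kappa_from_sd_deg(30)
#' @export
kappa_from_sd_deg <- function(sd) {
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("`sd` must be positive", call. = FALSE)
  }
  1 / (sd * pi / 180)^2
}

# log I0(kappa), stable for large kappa via the exponentially scaled Bessel
log_bessel_i0 <- function(kappa) {
  scaled <- besselI(kappa, 0, expon.scaled = TRUE)
  out <- kappa + log(scaled)
  # asymptotic fallback if the scaled Bessel underflows numerically
  bad <- !is.finite(out) | scaled <= 0
  out[bad] <- kappa[bad] - 0.5 * log(2 * pi * kappa[bad])
  out
}

#' Von Mises log-density on the degree scale
#'
#' Density per degree of a von Mises distribution with mean `mu` and
#' concentration `kappa_from_sd_deg(sigma)`; it integrates to 1 over any
#' 360-degree support.
#'
#' @param x Angles in degrees at which to evaluate.
#' @param mu Mean direction in degrees.
#' @param sigma Dispersion parameter in degrees (positive); the concentration
#'   is `1/sigma_rad^2`.
#' @return Log-density values (per degree).
#' @export
vonmises_logpdf <- function(x, mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  kappa <- kappa_from_sd_deg(sigma)
  delta <- (x - mu) * pi / 180
  kappa * cos(delta) - log(2 * pi) - log_bessel_i0(kappa) + log(pi / 180)
}

#' Draw von Mises random angles (degree scale)
#'
#' Best-Fisher rejection sampler. Draws are returned in degrees, wrapped to
#' `mu` plus a signed deviation in (-180, 180].
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param sigma Dispersion in degrees (positive), same convention as
#'   [vonmises_logpdf()].
#' @param seed Optional integer; when supplied the draw is made under a local
#'   RNG state so it is reproducible without disturbing the caller's stream.
#' @return Numeric vector of `n` angles in degrees.
#' @export
vonmises_sample <- function(n, mu = 0, sigma = 10, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  draw <- function() {
    kappa <- kappa_from_sd_deg(sigma)
    if (kappa > 5e5) {
      # effectively a narrow Gaussian; avoids degenerate rejection constants
      return(mu + stats::rnorm(n, 0, sigma))
    }
    tau <- 1 + sqrt(1 + 4 * kappa^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
    r <- (1 + rho^2) / (2 * rho)
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u1 <- stats::runif(1)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        u2 <- stats::runif(1)
        if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
      }
      out[i] <- sign(stats::runif(1) - 0.5) * acos(f) * 180 / pi + mu
    }
    out
  }
  ang <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  mu + wrap_signed(ang - mu)
}

#' Circular mean of directions
#'
#' @param x Angles in degrees.
#' @return Mean direction in degrees, in (-180, 180].
#' @export
circ_mean <- function(x) {
  r <- x * pi / 180
  wrap_signed(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Circular standard deviation of directions
#'
#' `sqrt(-2 log R)` on the radian scale, converted to degrees.
#'
#' @param x Angles in degrees.
#' @return Circular SD in degrees.
#' @export
circ_sd <- function(x) {
  r <- x * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Fisher-Lee circular correlation coefficient
#'
#' Correlation between two circular variables; invariant to constant rotation
#' of either input.
#'
#' @param x,y Angle vectors in degrees, equal length, at least 3 pairs.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
circ_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  a <- x * pi / 180
  b <- y * pi / 180
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - am)
  sb <- sin(b - bm)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}
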