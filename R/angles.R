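#' Axial (fiber) angle utilities
#'
#' Fibers are axial objects: an orientation angle is defined modulo 180
#' degrees (a fiber has no head or tail). All orientation statistics in this
#' package therefore use the angle-doubling construction: angles are doubled,
#' averaged as unit vectors on the circle, and the resultant halved. The
#' resultant length of the doubled-angle vectors is reported as *coherence*
#' (1 = perfectly aligned box, 0 = isotropic).
#'
#' @param theta Angles in degrees.
#' @return `wrap_axial()` returns angles reduced to `[0, 180)`.
#' @examples
#' wrap_axial(c(-10, 190, 90))
#' axial_mean(c(10, 170)) # 0, not 90: the axial mean respects the seam
#' @export
wrap_axial <- function(theta) {
  theta %% 180
}

#' @rdname wrap_axial
#' @param w Optional nonnegative weights, recycled against `theta`.
#' @return `axial_mean()` returns the weighted axial circular mean in
#'   `[0, 180)`, or `NA` if the total weight is zero.
#' @export
axial_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  keep <- !is.na(theta) & !is.na(w)
  theta <- theta[keep]; w <- w[keep]
  if (length(theta) == 0L || sum(w) <= 0) return(NA_real_)
  t2 <- 2 * theta * pi / 180
  wrap_axial(atan2(sum(w * sin(t2)), sum(w * cos(t2))) * 180 / pi / 2)
}

#' @rdname wrap_axial
#' @return `axial_coherence()` returns the resultant length of the
#'   doubled-angle unit vectors, in `[0, 1]`.
#' @export
axial_coherence <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  keep <- !is.na(theta) & !is.na(w)
  theta <- theta[keep]; w <- w[keep]
  if (length(theta) == 0L || sum(w) <= 0) return(NA_real_)
  t2 <- 2 * theta * pi / 180
  sqrt(sum(w * cos(t2))^2 + sum(w * sin(t2))^2) / sum(w)
}

#' @rdname wrap_axial
#' @param a,b Axial angles in degrees.
#' @return `axial_diff()` returns the absolute axial separation in
#'   `[0, 90]` degrees.
#' @export
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

#' Sample axial angles from a wrapped von Mises distribution
#'
#' Draws axial angles whose doubled values follow a von Mises distribution
#' with concentration `kappa` (Best-Fisher rejection sampling). `kappa = 0`
#' gives the isotropic axial distribution on `[0, 180)`; large `kappa`
#' concentrates tightly around `mu`.
#'
#' @param n Number of draws.
#' @param mu Mean axial angle, degrees.
#' @param kappa Concentration (of the doubled-angle von Mises), `>= 0`.
#' @return Numeric vector of axial angles in `[0, 180)`.
#' @export
rvonmises_axial <- function(n, mu = 90, kappa = 8) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(runif(n, 0, 180))
  mu2 <- 2 * mu * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      th2 <- (sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu2) %% (2 * pi)
      out[i] <- wrap_axial(th2 * 180 / pi / 2)
      i <- i + 1L
    }
  }
  out
}
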