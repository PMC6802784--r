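#' Direction of the sustained-to-transient weight gradient
#'
#' Fits the global linear field `omega ~ a + g . coords` by least squares and
#' returns the unit direction of steepest descent `-g / |g|`: the vector
#' points from sustained-rich (high omega) toward transient-rich (low omega)
#' tissue. A single dominant direction per structure is assumed.
#'
#' @param coordsMm voxel positions (mm), `n x 3` matrix in scanner axes
#'   (x = left-right, y = posterior-anterior, z = inferior-superior).
#' @param omega per-voxel sustained weights.
#' @return A [GradientVector-class].
#' @export
weightGradient <- function(coordsMm, omega) {
  coordsMm <- as.matrix(coordsMm)
  if (nrow(coordsMm) < 10L) stop("at least 10 voxels are required")
  if (nrow(coordsMm) != length(omega)) stop("one omega per voxel is required")
  X <- cbind(1, coordsMm)
  if (qr(X)$rank < 4L) stop("voxel coordinates are rank-deficient (collinear)")
  fit <- stats::lm.fit(X, omega)
  g <- fit$coefficients[-1L]
  mag <- sqrt(sum(g^2))
  if (mag < 1e-12 || !is.finite(mag))
    stop("omega field is constant; gradient direction undefined")
  r2 <- 1 - sum(fit$residuals^2) / sum((omega - mean(omega))^2)
  new("GradientVector", direction = unname(-g / mag), magnitude = mag, r2 = r2)
}

#' Coronal-plane angle of a gradient vector
#'
#' Projects the vector into the coronal (x-z) plane and measures the angle
#' from the horizontal, mapped to `[0, 360)`. For the left hemisphere the
#' lateral axis is sign-flipped so that dorsolateral-to-ventromedial
#' directions are comparable across hemispheres.
#'
#' @param v a [GradientVector-class] or a length-3 numeric vector.
#' @param hemisphere `"right"` (lateral = +x) or `"left"` (lateral = -x).
#' @return angle in degrees in `[0, 360)`.
#' @export
coronalAngle <- function(v, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  d <- if (is(v, "GradientVector")) v@direction else as.numeric(v)
  lateral <- if (hemisphere == "left") -d[1] else d[1]
  (atan2(d[3], lateral) * 180 / pi) %% 360
}

#' Circular mean direction with confidence interval
#'
#' Mean direction of the unit vectors of the angles, with a
#' dispersion-based confidence interval for the mean direction
#' (circular standard error `sqrt((1 - rho2) / (2 n Rbar^2))`, where `rho2`
#' is the mean resultant of the doubled angles), and the Rayleigh uniformity
#' test.
#'
#' @param anglesDeg angles in degrees.
#' @param confidence confidence level (default 0.95).
#' @return A [CircularSummary-class].
#' @export
circularMeanCi <- function(anglesDeg, confidence = 0.95) {
  n <- length(anglesDeg)
  if (n < 1L) stop("no angles supplied")
  th <- anglesDeg * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  rBar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  rho2 <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
  if (rBar > 1e-12) {
    sigma2 <- (1 - rho2) / (2 * n * rBar^2)
    zq <- stats::qnorm(1 - (1 - confidence) / 2)
    halfSin <- zq * sqrt(sigma2)
    half <- if (halfSin >= 1) pi else asin(halfSin)
  } else {
    half <- pi  # no preferred direction: CI covers the circle
  }
  meanDeg <- (mu * 180 / pi) %% 360
  ci <- c(meanDeg - half * 180 / pi, meanDeg + half * 180 / pi)
  new("CircularSummary", meanDeg = meanDeg, ciDeg = ci, rBar = rBar,
      rayleighP = rayleighTest(anglesDeg), n = as.integer(n))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle using `Z = n * Rbar^2` and the standard small-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Z n)) - (1 + 2n))`.
#'
#' @param anglesDeg angles in degrees.
#' @return p-value (clamped to `[0, 1]`).
#' @export
rayleighTest <- function(anglesDeg) {
  n <- length(anglesDeg)
  if (n < 2L) stop("at least 2 angles are required")
  th <- anglesDeg * pi / 180
  rBar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  Z <- n * rBar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z * n)) - (1 + 2 * n))
  min(max(p, 0), 1)
}
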