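#' Gaussian spatial receptive field on the model grid
#'
#' `G(x, y) = exp(-((x0 - x)^2 + (y0 - y)^2) / (2 * sigma^2))`, unnormalized
#' (peak value 1 at the center).
#'
#' @param x0,y0 center (deg).
#' @param sigma standard deviation (deg), positive.
#' @param geometry a [DisplayGeometry-class].
#' @return matrix (`gridNy x gridNx`) of field values in `(0, 1]`.
#' @export
spatialRF <- function(x0, y0, sigma, geometry = fieldGeometry()) {
  if (sigma <= 0) stop("sigma must be positive")
  g <- gridCoords(geometry)
  outer(
    exp(-(y0 - g$y)^2 / (2 * sigma^2)),
    exp(-(x0 - g$x)^2 / (2 * sigma^2))
  )
}

# Precomputed quantities for repeated predictions against one movie:
# the frames unrolled to a (nVol x nPix) matrix, pixel coordinates,
# per-volume channel gains and the HRF at TR resolution.
.modelContext <- function(movie, globals, rateHz = 480) {
  geom <- movie@geometry
  g <- gridCoords(geom)
  d <- dim(movie@frames)
  nVol <- d[3]
  fr <- matrix(aperm(movie@frames, c(3, 1, 2)), nrow = nVol)
  gains <- .volumeGains(movie@flickerTrack, globals, geom@trS, rateHz)
  list(
    frames = fr,
    pixY = rep(g$y, times = d[2]),
    pixX = rep(g$x, each = d[1]),
    cellArea = g$cellArea,
    gS = gains[, "gS"], gT = gains[, "gT"],
    hrf = doubleGammaHrf(globals@delta, geom@trS)@samples,
    trS = geom@trS, nVol = nVol, rateHz = rateHz,
    track = movie@flickerTrack, geometry = geom
  )
}

# Per-volume spatial overlap sum(S * G) * cellArea for one (x0, y0, sigma).
.spatialSeries <- function(ctx, x0, y0, sigma) {
  gvec <- exp(-((ctx$pixX - x0)^2 + (ctx$pixY - y0)^2) / (2 * sigma^2))
  as.numeric(ctx$frames %*% gvec) * ctx$cellArea
}

# Neural + hemodynamic stages given the spatial series.
.predictFromSpatial <- function(ctx, s, omega, beta = 1, mu = 0) {
  n <- s * (omega * ctx$gS + (1 - omega) * ctx$gT)
  b <- .causalConv(n, ctx$hrf)[, 1L]
  mu + beta * b
}

#' Forward BOLD prediction of the spatiotemporal pRF model
#'
#' Composes the model stages: per-volume spatial overlap of the stimulus
#' aperture with the Gaussian receptive field (inner product over grid cells
#' scaled by cell area), multiplication by the rectified sustained/transient
#' channel gains mixed by `omega`, causal convolution with the double-gamma
#' HRF (zero-padded start, truncated to the series length), then scaling by
#' `beta` and the baseline `mu`:
#' `R[i] = mu + beta * (HRF * (s * (omega * gS + (1 - omega) * gT)))[i]`.
#'
#' @param movie a [StimulusMovie-class].
#' @param params a [VoxelParams-class].
#' @param globals a [GlobalParams-class].
#' @param rateHz fine sampling rate for the temporal channels.
#' @return numeric vector of length `nVolumes(movie)`.
#' @examples
#' mov <- makeBarStimulus(fieldGeometry(spacingDeg = 1))
#' y <- predictBold(mov, voxelParams(2, 1, 1.5, omega = 0.8), globalParams())
#' @export
predictBold <- function(movie, params, globals, rateHz = 480) {
  validObject(params)
  ctx <- .modelContext(movie, globals, rateHz)
  s <- .spatialSeries(ctx, params@x0, params@y0, params@sigma)
  .predictFromSpatial(ctx, s, params@omega, params@beta, params@mu)
}
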