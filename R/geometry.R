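#' Construct a display/model-grid geometry
#'
#' Defaults describe a projected display subtending 26 x 20 degrees of visual
#' angle sampled at 0.25 deg per grid step (105 x 81 grid) with a 1.5 s TR.
#' Grid point counts must produce identical spacing along x and y; odd counts
#' keep fixation `(0,0)` on the grid.
#'
#' @param widthDeg,heightDeg display extent in degrees of visual angle.
#' @param gridNx,gridNy grid points along x and y.
#' @param trS volume duration (s).
#' @return A [DisplayGeometry-class] object.
#' @examples
#' geom <- displayGeometry()
#' gridSpacing(geom)
#' @export
displayGeometry <- function(widthDeg = 26, heightDeg = 20,
                            gridNx = 105L, gridNy = 81L, trS = 1.5) {
  gridNx <- as.integer(gridNx)
  gridNy <- as.integer(gridNy)
  dx <- widthDeg / (gridNx - 1L)
  dy <- heightDeg / (gridNy - 1L)
  if (abs(dx - dy) > 1e-9)
    stop("grid spacing must be identical in x and y (got ", signif(dx, 6),
         " vs ", signif(dy, 6), " deg); adjust gridNx/gridNy")
  new("DisplayGeometry", widthDeg = widthDeg, heightDeg = heightDeg,
      gridNx = gridNx, gridNy = gridNy, trS = trS)
}

#' Default square modeling field
#'
#' The central square of the display covering the `+/- fieldDeg/2` spatial
#' search range of the fit. The bar stimulus is generated on this field so
#' that a 5 deg bar sweeping edge-to-edge stimulates interior pixels for 25%
#' of the scan (the design duty cycle).
#'
#' @param fieldDeg field extent (deg); default 20 matches the `+/- 10` deg
#'   search bounds.
#' @param spacingDeg grid spacing (deg).
#' @param trS volume duration (s).
#' @return A square [DisplayGeometry-class].
#' @export
fieldGeometry <- function(fieldDeg = 20, spacingDeg = 0.25, trS = 1.5) {
  n <- as.integer(round(fieldDeg / spacingDeg)) + 1L
  displayGeometry(widthDeg = fieldDeg, heightDeg = fieldDeg,
                  gridNx = n, gridNy = n, trS = trS)
}

#' @describeIn displayGeometry grid spacing in degrees.
#' @param geometry a [DisplayGeometry-class].
#' @export
gridSpacing <- function(geometry) {
  geometry@widthDeg / (geometry@gridNx - 1L)
}

#' Grid coordinates of a geometry
#'
#' @param geometry a [DisplayGeometry-class].
#' @return list with `x` (length gridNx), `y` (length gridNy) pixel-center
#'   coordinates in degrees, and `cellArea` (deg^2).
#' @export
gridCoords <- function(geometry) {
  list(
    x = seq(-geometry@widthDeg / 2, geometry@widthDeg / 2,
            length.out = geometry@gridNx),
    y = seq(-geometry@heightDeg / 2, geometry@heightDeg / 2,
            length.out = geometry@gridNy),
    cellArea = gridSpacing(geometry)^2
  )
}

#' Construct yoked global parameters
#'
#' @param delta HRF delay (s) within `[-3, 3]`.
#' @param tau temporal dispersion; the sustained kernel is
#'   `exp(-(t - t0)^2 / (2 * pi * tau))`, so the effective Gaussian SD is
#'   `sqrt(pi * tau)` seconds. The default 2e-5 places the transient
#'   channel's band-pass peak near 20 Hz.
#' @return A [GlobalParams-class] object.
#' @export
globalParams <- function(delta = 0, tau = 2e-5) {
  new("GlobalParams", delta = delta, tau = tau)
}

#' Construct voxelwise pRF parameters
#'
#' @param x0,y0 pRF center (deg).
#' @param sigma spatial dispersion (deg), positive.
#' @param omega sustained weight in `[0, 1]`.
#' @param beta amplitude.
#' @param mu baseline.
#' @return A [VoxelParams-class] object.
#' @export
voxelParams <- function(x0 = 0, y0 = 0, sigma = 1, omega = 0.5,
                        beta = 1, mu = 0) {
  new("VoxelParams", x0 = unname(x0), y0 = unname(y0), sigma = unname(sigma),
      omega = unname(omega), beta = unname(beta), mu = unname(mu))
}

#' Construct a fit search space
#'
#' Spatial centers are bounded to `+/- xyBoundDeg` (the full-field extent of
#' the stimulus), omega to `[0, 1]` and sigma to `sigmaBounds`. The coarse
#' phase evaluates an `nXY x nXY x nSigma x nOmega` lattice (sigma points
#' log-spaced over `sigmaGridBounds`) and shrinks the bounds to the incumbent
#' cell's neighborhood for `passes - 1` further passes.
#'
#' @param xyBoundDeg spatial half-range (deg).
#' @param sigmaBounds hard sigma bounds for refinement.
#' @param nXY,nSigma,nOmega coarse lattice densities.
#' @param sigmaGridBounds sigma lattice range.
#' @param passes adaptive passes (>= 1).
#' @return A [SearchSpace-class] object.
#' @export
searchSpace <- function(xyBoundDeg = 10, sigmaBounds = c(0.05, 10),
                        nXY = 11L, nSigma = 8L, nOmega = 5L,
                        sigmaGridBounds = c(0.25, 8), passes = 2L) {
  new("SearchSpace", xyBoundDeg = xyBoundDeg, sigmaBounds = sigmaBounds,
      nXY = as.integer(nXY), nSigma = as.integer(nSigma),
      nOmega = as.integer(nOmega), sigmaGridBounds = sigmaGridBounds,
      passes = as.integer(passes))
}

#' @rdname VoxelParams-class
#' @param object,x a `VoxelParams`.
#' @export
setMethod("show", "VoxelParams", function(object) {
  cat(sprintf(
    "VoxelParams: center (%.3g, %.3g) deg, sigma %.3g deg, omega %.3g, beta %.3g, mu %.3g\n",
    object@x0, object@y0, object@sigma, object@omega, object@beta, object@mu))
})

#' Coerce voxel parameters to a named numeric vector
#'
#' @param params a [VoxelParams-class].
#' @return named numeric vector `(x0, y0, sigma, omega, beta, mu)`.
#' @export
paramVector <- function(params) {
  c(x0 = params@x0, y0 = params@y0, sigma = params@sigma,
    omega = params@omega, beta = params@beta, mu = params@mu)
}

#' @rdname DisplayGeometry-class
#' @param object a `DisplayGeometry`.
#' @export
setMethod("show", "DisplayGeometry", function(object) {
  cat(sprintf(
    "DisplayGeometry: %.3g x %.3g deg, grid %d x %d (%.4g deg/px), TR %.3g s\n",
    object@widthDeg, object@heightDeg, object@gridNx, object@gridNy,
    gridSpacing(object), object@trS))
})

#' @rdname GlobalParams-class
#' @param object a `GlobalParams`.
#' @export
setMethod("show", "GlobalParams", function(object) {
  cat(sprintf("GlobalParams: delta %.4g s, tau %.4g (SD %.4g ms)\n",
              object@delta, object@tau, 1000 * sqrt(pi * object@tau)))
})

#' @rdname StimulusMovie-class
#' @param object a `StimulusMovie`.
#' @export
setMethod("show", "StimulusMovie", function(object) {
  fr <- unique(object@flickerTrack)
  cat(sprintf(
    "StimulusMovie: %d volumes on a %d x %d grid; flicker frequencies {%s} Hz\n",
    dim(object@frames)[3], object@geometry@gridNy, object@geometry@gridNx,
    paste(sort(fr), collapse = ", ")))
})

#' @rdname PrfFitSet-class
#' @param object a `PrfFitSet`.
#' @export
setMethod("show", "PrfFitSet", function(object) {
  cat(sprintf(
    "PrfFitSet: %d voxels (%d with r2 > 0.1), delta %.4g s, tau %.4g, %d outer iterations%s\n",
    nrow(object@fits), sum(object@fits$r2 > 0.1, na.rm = TRUE),
    object@globals@delta, object@globals@tau, max(object@trace$iteration),
    if (isTRUE(object@converged)) "" else " (not converged)"))
})

#' @rdname Phantom-class
#' @param object a `Phantom`.
#' @export
setMethod("show", "Phantom", function(object) {
  cat(sprintf(
    "Phantom: %d voxels, %s hemisphere, %.3g mm lattice, volume %.3g mm^3\n",
    nrow(object@coords), object@hemisphere, object@voxelSizeMm,
    nrow(object@coords) * object@voxelSizeMm^3))
})

#' @rdname ClusterResult-class
#' @param object a `ClusterResult`.
#' @export
setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d voxels in %d clusters (%s linkage); sizes %s\n",
              length(object@labels), object@k, object@linkage,
              paste(tabulate(object@labels, object@k), collapse = "/")))
})

#' @rdname CircularSummary-class
#' @param object a `CircularSummary`.
#' @export
setMethod("show", "CircularSummary", function(object) {
  cat(sprintf(
    "CircularSummary: mean %.1f deg (95%% CI %.1f-%.1f), Rbar %.3f, Rayleigh p %.3g, n %d\n",
    object@meanDeg, object@ciDeg[1], object@ciDeg[2], object@rBar,
    object@rayleighP, object@n))
})

# ---- accessors ----

#' Accessors for stimulus movies and fit sets
#'
#' @param x object to access.
#' @return `frames()` the aperture array; `flickerTrack()` the per-volume
#'   flicker frequencies; `movieGeometry()` the grid geometry; `nVolumes()`
#'   the number of volumes; `fitTable()` the per-voxel fit data.frame;
#'   `fitGlobals()` the yoked [GlobalParams-class]; `truthParams()` a
#'   phantom's ground-truth table; `voxelCoords()` its mm coordinates;
#'   `clusterLabels()` integer cluster labels.
#' @name accessors
NULL

#' @rdname accessors
#' @export
frames <- function(x) x@frames

#' @rdname accessors
#' @export
flickerTrack <- function(x) x@flickerTrack

#' @rdname accessors
#' @export
movieGeometry <- function(x) x@geometry

#' @rdname accessors
#' @export
nVolumes <- function(x) dim(x@frames)[3]

#' @rdname accessors
#' @export
fitTable <- function(x) x@fits

#' @rdname accessors
#' @export
fitGlobals <- function(x) x@globals

#' @rdname accessors
#' @export
truthParams <- function(x) x@truth

#' @rdname accessors
#' @export
voxelCoords <- function(x) x@coords

#' @rdname accessors
#' @export
clusterLabels <- function(x) x@labels

#' @rdname accessors
#' @export
scheduleTable <- function(x) x@trials
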