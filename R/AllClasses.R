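#' @import methods
NULL

#' Display and model-grid geometry
#'
#' Describes the projected display (in degrees of visual angle) and the
#' rectangular grid on which stimulus apertures and spatial receptive fields
#' are evaluated, together with the volume acquisition time (TR).
#'
#' The grid is defined by pixel centers spanning `[-widthDeg/2, widthDeg/2]`
#' horizontally and `[-heightDeg/2, heightDeg/2]` vertically, with fixation at
#' `(0, 0)`, x increasing rightward and y increasing upward. Constructors
#' enforce equal grid spacing along x and y.
#'
#' @slot widthDeg horizontal extent in degrees of visual angle.
#' @slot heightDeg vertical extent in degrees of visual angle.
#' @slot gridNx,gridNy number of grid points along x and y.
#' @slot trS volume acquisition duration (TR) in seconds.
#' @export
setClass("DisplayGeometry",
  representation(
    widthDeg = "numeric", heightDeg = "numeric",
    gridNx = "integer", gridNy = "integer", trS = "numeric"
  )
)

setValidity("DisplayGeometry", function(object) {
  msg <- character()
  if (length(object@widthDeg) != 1L || !is.finite(object@widthDeg) || object@widthDeg <= 0)
    msg <- c(msg, "widthDeg must be a positive scalar")
  if (length(object@heightDeg) != 1L || !is.finite(object@heightDeg) || object@heightDeg <= 0)
    msg <- c(msg, "heightDeg must be a positive scalar")
  if (length(object@trS) != 1L || !is.finite(object@trS) || object@trS <= 0)
    msg <- c(msg, "trS must be a positive scalar")
  if (object@gridNx < 2L || object@gridNy < 2L)
    msg <- c(msg, "grid must have at least 2 points per axis")
  if (length(msg)) msg else TRUE
})

#' Stimulus aperture movie with flicker encoding
#'
#' A stimulus movie over the model grid at volume (TR) resolution. `frames`
#' holds the aperture (1 inside the stimulated region, 0 outside; values in
#' `[0, 1]` after spatial downsampling) as a `ny x nx x nVolumes` array.
#' `flickerTrack` gives the flicker frequency (Hz) displayed during each
#' volume, 0 when no stimulus is present.
#'
#' @slot frames numeric array, `ny x nx x nVolumes`, values in `[0, 1]`.
#' @slot geometry the [DisplayGeometry-class] the frames are sampled on.
#' @slot flickerTrack numeric vector of per-volume flicker frequencies (Hz).
#' @export
setClass("StimulusMovie",
  representation(
    frames = "array", geometry = "DisplayGeometry", flickerTrack = "numeric"
  )
)

setValidity("StimulusMovie", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3D array (ny x nx x nVolumes)")
  else {
    if (d[1] != object@geometry@gridNy || d[2] != object@geometry@gridNx)
      msg <- c(msg, "frames dimensions do not match geometry grid")
    if (length(object@flickerTrack) != d[3])
      msg <- c(msg, "flickerTrack length must equal the number of volumes")
  }
  rng <- range(object@frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "frames values must lie in [0, 1]")
  if (any(object@flickerTrack < 0))
    msg <- c(msg, "flickerTrack must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Full-field trial schedule
#'
#' An ordered, non-overlapping sequence of full-field stimulation trials. Each
#' trial carries an onset, a duration and a flicker frequency; isoluminance
#' schedules additionally carry a spatial frequency (cycles/deg) and a green
#' luminance offset expressed as a fraction of the isoluminant reference.
#'
#' @slot trials data.frame with columns `onset_s`, `duration_s`, `flicker_hz`,
#'   `sf_cpd`, `lum_offset` (the latter two may be `NA`).
#' @export
setClass("TrialSchedule", representation(trials = "data.frame"))

setValidity("TrialSchedule", function(object) {
  tr <- object@trials
  need <- c("onset_s", "duration_s", "flicker_hz", "sf_cpd", "lum_offset")
  if (!all(need %in% names(tr)))
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(tr) > 1L) {
    if (any(diff(tr$onset_s) <= 0))
      msg <- c(msg, "trial onsets must be strictly increasing")
    ends <- tr$onset_s + tr$duration_s
    if (any(tr$onset_s[-1L] < ends[-nrow(tr)] - 1e-9))
      msg <- c(msg, "trials must not overlap")
  }
  if (any(tr$duration_s <= 0)) msg <- c(msg, "durations must be positive")
  if (any(tr$flicker_hz < 0)) msg <- c(msg, "flicker frequencies must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Fine-time luminance modulation waveform
#'
#' The sinusoidal luminance modulation of the stimulus sampled on a fine time
#' grid (well above the flicker Nyquist rate), used to drive the temporal
#' channels of the model.
#'
#' @slot samples numeric vector of luminance modulation values in `[-1, 1]`.
#' @slot rateHz fine sampling rate in Hz.
#' @export
setClass("FineWaveform", representation(samples = "numeric", rateHz = "numeric"))

setValidity("FineWaveform", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a positive scalar")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-9)
    msg <- c(msg, "samples must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Temporal kernel sampled on a fine grid
#'
#' A temporal receptive-field or hemodynamic kernel. Sustained/transient
#' channel kernels span one volume acquisition and are centered at `t0`;
#' the hemodynamic kernel is causal with `t0 = 0`.
#'
#' @slot samples kernel values.
#' @slot rateHz sampling rate (Hz).
#' @slot t0 kernel center (s) relative to the first sample.
#' @export
setClass("TemporalKernel",
  representation(samples = "numeric", rateHz = "numeric", t0 = "numeric")
)

setValidity("TemporalKernel", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a positive scalar")
  if (length(object@samples) < 3L)
    msg <- c(msg, "kernel must have at least 3 samples")
  if (length(msg)) msg else TRUE
})

#' Session-wide yoked model parameters
#'
#' The hemodynamic response delay `delta` (seconds, shift of the double-gamma
#' peak) and the temporal receptive-field dispersion `tau`. Both are shared
#' (yoked) across all voxels of a session and estimated in tandem with the
#' voxelwise parameters. `tau` enters the sustained kernel through the
#' exponent `-(t - t0)^2 / (2 * pi * tau)` and carries no physiological
#' interpretation.
#'
#' @slot delta HRF delay in seconds, constrained to `[-3, 3]`.
#' @slot tau temporal dispersion (s^2 / pi scale), positive.
#' @export
setClass("GlobalParams", representation(delta = "numeric", tau = "numeric"))

setValidity("GlobalParams", function(object) {
  msg <- character()
  if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0)
    msg <- c(msg, "tau must be a positive scalar")
  if (length(object@delta) != 1L || !is.finite(object@delta) ||
      abs(object@delta) > 3 + 1e-9)
    msg <- c(msg, "delta must lie within [-3, 3] s")
  if (length(msg)) msg else TRUE
})

#' Voxelwise pRF parameters
#'
#' The six per-voxel parameters of the spatiotemporal pRF model: visual-field
#' center `(x0, y0)` in degrees, spatial dispersion `sigma` (deg), the
#' transient-sustained mixture `omega` (1 = purely sustained, 0 = purely
#' transient), the BOLD amplitude `beta` and the baseline `mu`.
#'
#' @slot x0,y0 pRF center in degrees of visual angle.
#' @slot sigma spatial standard deviation in degrees, positive.
#' @slot omega sustained weight in `[0, 1]`.
#' @slot beta amplitude (arbitrary BOLD units).
#' @slot mu baseline (same units as the data).
#' @export
setClass("VoxelParams",
  representation(
    x0 = "numeric", y0 = "numeric", sigma = "numeric",
    omega = "numeric", beta = "numeric", mu = "numeric"
  )
)

setValidity("VoxelParams", function(object) {
  msg <- character()
  sc <- vapply(
    c("x0", "y0", "sigma", "omega", "beta", "mu"),
    function(s) length(slot(object, s)) == 1L && is.finite(slot(object, s)),
    logical(1)
  )
  if (!all(sc)) msg <- c(msg, "all parameters must be finite scalars")
  else {
    if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
    if (object@omega < 0 || object@omega > 1)
      msg <- c(msg, "omega must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Search space for the two-phase fit
#'
#' Bounds and coarse-grid densities used by [coarseGridFit()] and
#' [simplexRefine()]. Spatial centers are searched within `+/- xyBoundDeg` of
#' fixation, `sigma` within `sigmaBounds`, `omega` within `[0, 1]`.
#'
#' @slot xyBoundDeg spatial search half-width (deg), default 10.
#' @slot sigmaBounds length-2 bounds for sigma (deg).
#' @slot nXY,nSigma,nOmega coarse lattice densities per dimension.
#' @slot sigmaGridBounds length-2 range of the (log-spaced) sigma lattice.
#' @slot passes number of adaptive grid passes.
#' @export
setClass("SearchSpace",
  representation(
    xyBoundDeg = "numeric", sigmaBounds = "numeric",
    nXY = "integer", nSigma = "integer", nOmega = "integer",
    sigmaGridBounds = "numeric", passes = "integer"
  )
)

setValidity("SearchSpace", function(object) {
  msg <- character()
  if (object@xyBoundDeg <= 0) msg <- c(msg, "xyBoundDeg must be positive")
  if (length(object@sigmaBounds) != 2L || object@sigmaBounds[1] <= 0 ||
      diff(object@sigmaBounds) <= 0)
    msg <- c(msg, "sigmaBounds must be an increasing positive pair")
  if (length(object@sigmaGridBounds) != 2L || object@sigmaGridBounds[1] <= 0 ||
      diff(object@sigmaGridBounds) <= 0)
    msg <- c(msg, "sigmaGridBounds must be an increasing positive pair")
  if (object@nXY < 2L || object@nSigma < 2L || object@nOmega < 2L)
    msg <- c(msg, "lattice densities must be at least 2")
  if (object@passes < 1L) msg <- c(msg, "passes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of fitting one voxel
#'
#' @slot params the fitted [VoxelParams-class].
#' @slot rss residual sum of squares.
#' @slot r2 variance explained, `1 - RSS / sum((y - mean(y))^2)`.
#' @slot nIterations objective evaluations used by the simplex phase.
#' @slot converged logical convergence flag from the simplex phase.
#' @export
setClass("FitResult",
  representation(
    params = "VoxelParams", rss = "numeric", r2 = "numeric",
    nIterations = "integer", converged = "logical"
  )
)

setValidity("FitResult", function(object) {
  if (length(object@r2) == 1L && is.finite(object@r2) && object@r2 > 1 + 1e-9)
    "r2 cannot exceed 1" else TRUE
})

#' Yoked fit of a voxel set
#'
#' Per-voxel parameter estimates together with the session-wide yoked
#' globals and the outer-iteration trace of the alternating scheme.
#'
#' @slot fits data.frame with one row per voxel: `x0, y0, sigma, omega, beta,
#'   mu, rss, r2, converged, skipped`.
#' @slot globals final [GlobalParams-class].
#' @slot trace data.frame logging `(iteration, delta, tau, rss)` per outer step.
#' @slot converged logical, whether the yoking loop met its tolerance.
#' @export
setClass("PrfFitSet",
  representation(
    fits = "data.frame", globals = "GlobalParams",
    trace = "data.frame", converged = "logical"
  )
)

#' Synthetic voxel-lattice phantom
#'
#' A phantom emulating an LGN-like voxel population: an ellipsoidal mask on a
#' millimeter lattice with smooth ground-truth parameter fields (retinotopic
#' eccentricity/polar-angle maps, a sigma-vs-eccentricity slope, a planted
#' coronal sustained-to-transient weight gradient and a ventromedial
#' amplitude bump emulating the vascular hilum).
#'
#' @slot coords voxel centers (mm), `n x 3` matrix, columns
#'   (lateral x, anterior y, superior z).
#' @slot truth data.frame of ground-truth `VoxelParams` fields per voxel.
#' @slot globals true [GlobalParams-class].
#' @slot dims integer lattice dimensions.
#' @slot maskIdx linear lattice indices of in-mask voxels.
#' @slot voxelSizeMm lattice spacing (mm).
#' @slot hemisphere `"left"` or `"right"`.
#' @slot config the generating configuration list.
#' @export
setClass("Phantom",
  representation(
    coords = "matrix", truth = "data.frame", globals = "GlobalParams",
    dims = "integer", maskIdx = "integer", voxelSizeMm = "numeric",
    hemisphere = "character", config = "list"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (nrow(object@coords) != nrow(object@truth))
    msg <- c(msg, "coords and truth must have one row per voxel")
  need <- c("x0", "y0", "sigma", "omega", "beta", "mu")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, "truth must contain x0, y0, sigma, omega, beta, mu")
  else if (!all(vapply(object@truth[need], function(v) all(is.finite(v)), logical(1))))
    msg <- c(msg, "truth fields must be finite")
  if (length(object@maskIdx) != nrow(object@coords))
    msg <- c(msg, "maskIdx must index every phantom voxel")
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Agglomerative clustering result
#'
#' @slot labels integer cluster labels in `1..k`, one per voxel.
#' @slot D symmetric dissimilarity matrix with zero diagonal.
#' @slot linkage linkage criterion used.
#' @slot k number of clusters.
#' @slot hclust the merge tree as returned by [stats::hclust()].
#' @export
setClass("ClusterResult",
  representation(
    labels = "integer", D = "matrix", linkage = "character",
    k = "integer", hclust = "ANY"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (!isTRUE(all.equal(dim(object@D), c(n, n))))
    msg <- c(msg, "D must be n x n for n labeled voxels")
  else {
    if (max(abs(object@D - t(object@D))) > 1e-8)
      msg <- c(msg, "D must be symmetric")
    if (max(abs(diag(object@D))) > 1e-8)
      msg <- c(msg, "D must have zero diagonal")
  }
  if (length(unique(object@labels)) != object@k)
    msg <- c(msg, "all k clusters must be non-empty")
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Weight-gradient direction
#'
#' Direction of steepest descent of the sustained weight across voxel
#' coordinates: the unit vector points from sustained-rich (high omega)
#' toward transient-rich (low omega) tissue, in scanner axes
#' (x = left-right, y = posterior-anterior, z = inferior-superior).
#'
#' @slot direction unit 3-vector.
#' @slot magnitude gradient magnitude (delta omega per mm).
#' @slot r2 variance of omega explained by the planar fit.
#' @export
setClass("GradientVector",
  representation(direction = "numeric", magnitude = "numeric", r2 = "numeric")
)

setValidity("GradientVector", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    "direction must be a unit vector" else TRUE
})

#' Circular summary of a set of angles
#'
#' @slot meanDeg circular mean direction in `[0, 360)`.
#' @slot ciDeg length-2 confidence interval for the mean direction (deg).
#' @slot rBar mean resultant length in `[0, 1]`.
#' @slot rayleighP Rayleigh uniformity test p-value.
#' @slot n number of angles.
#' @export
setClass("CircularSummary",
  representation(
    meanDeg = "numeric", ciDeg = "numeric", rBar = "numeric",
    rayleighP = "numeric", n = "integer"
  )
)

setValidity("CircularSummary", function(object) {
  msg <- character()
  if (object@rBar < -1e-9 || object@rBar > 1 + 1e-9)
    msg <- c(msg, "rBar must lie in [0, 1]")
  if (length(object@ciDeg) != 2L)
    msg <- c(msg, "ciDeg must have length 2")
  if (length(msg)) msg else TRUE
})

#' Bootstrap reliability curves
#'
#' Stability of pRF parameter estimates as a function of the number of
#' averaged runs: for each (parameter, sample size), the mean absolute
#' deviation of the resampled estimate from the all-runs reference estimate,
#' with a percentile interval over replicates.
#'
#' @slot summary data.frame: `parameter, size, mean_abs_dev, lo, hi, reps`.
#' @slot long data.frame: per-replicate deviations
#'   (`parameter, size, replicate, voxel, deviation`).
#' @slot reference the all-runs reference [PrfFitSet-class] fit table.
#' @export
setClass("ReliabilityCurve",
  representation(summary = "data.frame", long = "data.frame", reference = "data.frame")
)
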