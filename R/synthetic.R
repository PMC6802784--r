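#' Phantom configuration
#'
#' Default configuration of the synthetic LGN-like phantom: an ellipsoidal
#' mask of roughly 250 mm^3 on a 1.5 mm lattice with smooth ground-truth
#' fields emulating the reported organization — eccentricity growing along
#' the posterior-to-anterior axis (foveal representations at the posterior
#' pole), receptive-field size increasing linearly with eccentricity, a
#' sustained-to-transient weight gradient planted in the coronal plane, and
#' an amplitude (vascular gain) bump at the ventromedial "hilum".
#'
#' @param voxelSizeMm lattice spacing (mm).
#' @param semiAxesMm ellipsoid semi-axes (mm), order (lateral, anterior,
#'   superior); defaults give ~250 mm^3.
#' @param hemisphere `"right"` or `"left"` (mirrors the lateral axis).
#' @param eccRangeDeg eccentricity range mapped along the anterior axis.
#' @param polarSpanDeg polar-angle span (deg) of the represented
#'   contralateral hemifield.
#' @param sigmaIntercept,sigmaSlope receptive-field size model
#'   `sigma = intercept + slope * ecc`.
#' @param omegaAngleDeg coronal-plane angle (deg from horizontal) of the
#'   planted sustained-to-transient gradient.
#' @param omegaRange range of the planted weight field (clipped to `[0, 1]`).
#' @param hilumOffset hilum center as fractions of the semi-axes
#'   (medial/ventral by default).
#' @param hilumWidthMm Gaussian width (mm) of the amplitude bump.
#' @param hilumHeight amplitude bump height relative to `betaBase`.
#' @param betaBase baseline amplitude.
#' @param baseline BOLD baseline `mu`.
#' @param delta,tau true yoked globals.
#' @return named list of configuration values.
#' @export
phantomConfig <- function(voxelSizeMm = 1.5,
                          semiAxesMm = c(5.0, 3.3, 3.6),
                          hemisphere = "right",
                          eccRangeDeg = c(0.75, 8),
                          polarSpanDeg = 160,
                          sigmaIntercept = 0.5, sigmaSlope = 0.4,
                          omegaAngleDeg = 36,
                          omegaRange = c(0.15, 0.85),
                          hilumOffset = c(-0.4, 0, -0.6),
                          hilumWidthMm = 2,
                          hilumHeight = 1,
                          betaBase = 1,
                          baseline = 100,
                          delta = 0, tau = 2e-5) {
  as.list(environment())
}

#' Generate a ground-truth phantom
#'
#' Builds the voxel lattice, mask and smooth truth fields described by
#' [phantomConfig()]. The truth fields are deterministic functions of the
#' configuration; `seed` controls only the optional field jitter.
#'
#' @param config a [phantomConfig()] list.
#' @param seed integer seed (used when `jitterSd > 0`).
#' @param jitterSd SD of optional Gaussian jitter added to the omega field.
#' @return A [Phantom-class].
#' @export
makePhantom <- function(config = phantomConfig(), seed = 1L, jitterSd = 0) {
  ax <- config$semiAxesMm
  vs <- config$voxelSizeMm
  half <- ceiling(ax / vs)
  dims <- as.integer(2L * half + 1L)
  gx <- (seq_len(dims[1]) - half[1] - 1L) * vs
  gy <- (seq_len(dims[2]) - half[2] - 1L) * vs
  gz <- (seq_len(dims[3]) - half[3] - 1L) * vs
  coords <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                                  KEEP.OUT.ATTRS = FALSE))
  inMask <- rowSums(sweep(coords, 2L, ax, "/")^2) <= 1
  maskIdx <- which(inMask)
  coords <- coords[inMask, , drop = FALSE]
  n <- nrow(coords)

  latSign <- if (config$hemisphere == "left") -1 else 1
  latn <- latSign * coords[, 1] / ax[1]   # +1 = lateral
  apn <- coords[, 2] / ax[2]              # +1 = anterior
  zn <- coords[, 3] / ax[3]               # +1 = superior

  # eccentricity grows posterior -> anterior (foveal at the posterior pole)
  ecc <- config$eccRangeDeg[1] +
    diff(config$eccRangeDeg) * (apn + 1) / 2
  # polar angle along the superior-medial -> inferior-lateral axis, covering
  # the contralateral hemifield
  u <- ((latn - zn) / 2 + 1) / 2          # 0..1
  span <- config$polarSpanDeg
  polar <- if (config$hemisphere == "right") (180 - span / 2) + span * u
           else (-span / 2) + span * u
  x0 <- ecc * cos(polar * pi / 180)
  y0 <- ecc * sin(polar * pi / 180)
  sigma <- config$sigmaIntercept + config$sigmaSlope * ecc

  # planted coronal-plane weight gradient (sustained -> transient along
  # (cos angle, sin angle) in the (lateral, superior) plane). The field is
  # linear in millimeter coordinates so the mm-space gradient direction is
  # exactly the configured angle (a field linear in the axis-normalized
  # coordinates would be tilted by the unequal semi-axes).
  th <- config$omegaAngleDeg * pi / 180
  t_ <- cos(th) * (latSign * coords[, 1]) + sin(th) * coords[, 3]
  t_ <- t_ / max(abs(t_))
  mid <- mean(config$omegaRange)
  omega <- mid - diff(config$omegaRange) / 2 * t_
  if (jitterSd > 0)
    omega <- omega + .withSeed(seed, stats::rnorm(n, 0, jitterSd))
  omega <- pmin(pmax(omega, 0), 1)

  hc <- config$hilumOffset * ax * c(latSign, 1, 1)
  d2 <- rowSums(sweep(coords, 2L, hc)^2)
  beta <- config$betaBase *
    (1 + config$hilumHeight * exp(-d2 / (2 * config$hilumWidthMm^2)))

  truth <- data.frame(x0 = x0, y0 = y0, sigma = sigma, omega = omega,
                      beta = beta, mu = rep(config$baseline, n),
                      ecc = ecc, polar = polar %% 360)
  new("Phantom", coords = coords, truth = truth,
      globals = globalParams(config$delta, config$tau),
      dims = dims, maskIdx = as.integer(maskIdx), voxelSizeMm = vs,
      hemisphere = config$hemisphere, config = config)
}

# Smooth motion drift plus planted step spikes exceeding the FD threshold.
.simulateMotion <- function(nVol, nSpikes = 0L, spikeMm = 0.6,
                            driftSd = 0.003) {
  tr <- matrix(0, nVol, 6L)
  for (j in 1:3) tr[, j] <- cumsum(stats::rnorm(nVol, 0, driftSd))
  for (j in 4:6) tr[, j] <- cumsum(stats::rnorm(nVol, 0, driftSd / 50))
  if (nSpikes > 0L) {
    cand <- seq(5L, nVol - 2L)
    at <- integer(0)
    while (length(at) < nSpikes) {
      k <- sample(cand, 1L)
      if (!length(at) || min(abs(at - k)) > 2L) at <- c(at, k)
    }
    for (k in at) tr[k:nVol, 1] <- tr[k:nVol, 1] + spikeMm
  }
  colnames(tr) <- c("trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")
  tr
}

#' Simulate multi-run BOLD data from a phantom
#'
#' Runs the forward model per voxel from the phantom's truth fields and adds
#' Gaussian noise (optionally AR(1)). Noise is configured either by a fixed
#' SD or by a per-voxel signal-to-noise ratio
#' `snr = sd(beta * b) / noiseSd`. Each run gets `discardFirst` pre-stimulus
#' baseline volumes and a smooth motion trace with `motionSpikes` planted
#' step displacements exceeding 0.4 mm FD.
#'
#' @param phantom a [Phantom-class].
#' @param movie a [StimulusMovie-class] driving the responses.
#' @param noise list with `sd` (fixed SD) or `snr` (per-voxel calibration),
#'   and optional `ar1` coefficient.
#' @param nRuns number of runs.
#' @param seed integer seed.
#' @param discardFirst pre-stimulus baseline volumes per run (default 4).
#' @param motionSpikes planted motion spikes per run (default 0).
#' @param rateHz fine channel sampling rate.
#' @return A `SummarizedExperiment`: one assay per run (voxel x time,
#'   including the `discardFirst` baseline volumes), truth fields in
#'   `rowData`, flicker in `colData`, motion traces / globals / noise
#'   settings in `metadata`.
#' @export
simulateRuns <- function(phantom, movie, noise = list(sd = 0, ar1 = 0),
                         nRuns = 1L, seed = 1L, discardFirst = 4L,
                         motionSpikes = 0L, rateHz = 480) {
  truth <- phantom@truth
  nVox <- nrow(truth)
  ctx <- .modelContext(movie, phantom@globals, rateHz)
  pred <- vapply(seq_len(nVox), function(v) {
    s <- .spatialSeries(ctx, truth$x0[v], truth$y0[v], truth$sigma[v])
    .predictFromSpatial(ctx, s, truth$omega[v], truth$beta[v], truth$mu[v])
  }, numeric(ctx$nVol))              # nVol x nVox
  ar1 <- if (is.null(noise$ar1)) 0 else noise$ar1
  sdVox <- if (!is.null(noise$snr) && noise$snr > 0) {
    apply(pred, 2L, stats::sd) / noise$snr
  } else rep(if (is.null(noise$sd)) 0 else noise$sd, nVox)

  nT <- ctx$nVol + discardFirst
  full <- if (discardFirst > 0L)
    rbind(matrix(truth$mu, nrow = discardFirst, ncol = nVox, byrow = TRUE),
          pred) else pred
  out <- .withSeed(seed, {
    runs <- vector("list", nRuns)
    motion <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
      eps <- matrix(stats::rnorm(nT * nVox), nT, nVox)
      if (ar1 != 0) {
        eps <- apply(eps, 2L, function(e)
          as.numeric(stats::filter(e, ar1, method = "recursive")))
        eps <- eps * sqrt(1 - ar1^2)   # restore unit marginal variance
      }
      runs[[r]] <- t(full + sweep(eps, 2L, sdVox, "*"))
      motion[[r]] <- .simulateMotion(nT, nSpikes = motionSpikes)
    }
    list(runs = runs, motion = motion)
  })
  names(out$runs) <- sprintf("run%02d", seq_len(nRuns))
  names(out$motion) <- names(out$runs)
  colDat <- S4Vectors::DataFrame(
    volume = seq_len(nT),
    flicker_hz = c(rep(0, discardFirst), ctx$track),
    prestim = seq_len(nT) <= discardFirst)
  SummarizedExperiment::SummarizedExperiment(
    assays = out$runs,
    rowData = S4Vectors::DataFrame(truth, coords = I(phantom@coords)),
    colData = colDat,
    metadata = list(globals = phantom@globals, motion = out$motion,
                    noise = list(sdVox = sdVox, ar1 = ar1),
                    seed = seed, discardFirst = discardFirst,
                    hemisphere = phantom@hemisphere))
}

#' Phantom with planted response families for clustering
#'
#' Generates full-field voxel time-series in `k` families that differ in one
#' driving parameter — amplitude (`"beta"`, emulating the vascular hilum
#' gain) or temporal weight (`"omega"`) — with all other pRF parameters drawn
#' independently of the family. Returns the series, the ground-truth labels
#' and the per-voxel parameter table.
#'
#' @param nPerGroup voxels per family.
#' @param driver `"beta"` or `"omega"`.
#' @param levels driving parameter value per family (length = k). The
#'   amplitude default `c(6, 0.8, 0.05)` plants a strongly driven, a
#'   moderately driven and an effectively unstimulated tier.
#' @param schedule a [TrialSchedule-class]; default full-field flicker
#'   schedule.
#' @param noiseScale additive noise SD as a multiple of the unit-amplitude
#'   signal SD, so a voxel's SNR is approximately `beta / noiseScale`.
#' @param baseline BOLD baseline.
#' @param globals a [GlobalParams-class].
#' @param seed integer seed.
#' @param rateHz fine channel sampling rate.
#' @return list with `ts` (voxel x time), `labels`, `params` (per-voxel
#'   truth), `movie`, `noiseSd`.
#' @export
makeClusterPhantom <- function(nPerGroup = 25L,
                               driver = c("beta", "omega"),
                               levels = NULL,
                               schedule = makeFullfieldSchedule(seed = 7L),
                               noiseScale = 1,
                               baseline = 100,
                               globals = globalParams(),
                               seed = 1L, rateHz = 480) {
  driver <- match.arg(driver)
  if (is.null(levels))
    levels <- if (driver == "beta") c(6, 0.8, 0.05) else c(0.9, 0.5, 0.1)
  k <- length(levels)
  n <- k * nPerGroup
  labels <- rep(seq_len(k), each = nPerGroup)
  geom <- fieldGeometry(spacingDeg = 5)   # full-field: spatial grid is moot
  movie <- fullfieldMovie(schedule, geom)
  ctx <- .modelContext(movie, globals, rateHz)
  s0 <- .spatialSeries(ctx, 0, 0, 3)      # common full-field spatial drive
  noiseSd <- noiseScale * stats::sd(.predictFromSpatial(ctx, s0, 0.5, 1, 0))

  .withSeed(seed, {
    params <- data.frame(
      x0 = stats::runif(n, -6, 6), y0 = stats::runif(n, -6, 6),
      sigma = stats::runif(n, 0.5, 3),
      omega = if (driver == "omega") levels[labels]
              else stats::runif(n, 0.3, 0.7),
      beta = if (driver == "beta") levels[labels]
             else rep(1, n),
      mu = rep(baseline, n))
    ts <- t(vapply(seq_len(n), function(v) {
      .predictFromSpatial(ctx, s0, params$omega[v], params$beta[v],
                          params$mu[v]) +
        stats::rnorm(ctx$nVol, 0, noiseSd)
    }, numeric(ctx$nVol)))
    list(ts = ts, labels = labels, params = params, movie = movie,
         noiseSd = noiseSd)
  })
}
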