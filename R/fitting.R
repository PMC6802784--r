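#' Residual sum of squares
#'
#' @param pred,obs equal-length numeric vectors.
#' @return `sum((obs - pred)^2)`.
#' @export
rss <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length")
  sum((obs - pred)^2)
}

#' Spatially downsample a stimulus movie
#'
#' Bilinear (separable two-axis linear) interpolation of every frame onto a
#' grid with `fraction` of the original points per axis (at least 3), with
#' the field extent preserved. Used by the coarse fitting phase, which runs
#' at 5% of the stimulus resolution.
#'
#' @param movie a [StimulusMovie-class].
#' @param fraction resolution fraction in `(0, 1]`.
#' @return A [StimulusMovie-class] on the reduced grid (frame values lie in
#'   `[0, 1]` but are no longer binary).
#' @export
downsampleStimulus <- function(movie, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(movie)
  geom <- movie@geometry
  # never drop below 11 points per axis (or the original grid, if smaller):
  # a coarser reduction loses the bar position entirely on modest grids
  nxNew <- min(geom@gridNx, max(11L, as.integer(round(geom@gridNx * fraction))))
  nyNew <- min(geom@gridNy, max(11L, as.integer(round(geom@gridNy * fraction))))
  if (nxNew < 3L || nyNew < 3L) stop("downsampled grid must be at least 3 x 3")
  g <- gridCoords(geom)
  xNew <- seq(g$x[1], g$x[length(g$x)], length.out = nxNew)
  yNew <- seq(g$y[1], g$y[length(g$y)], length.out = nyNew)
  nVol <- dim(movie@frames)[3]
  out <- array(0, dim = c(nyNew, nxNew, nVol))
  for (v in seq_len(nVol)) {
    f <- movie@frames[, , v]
    # interpolate along x (columns), then along y (rows)
    fx <- t(apply(f, 1L, function(row) stats::approx(g$x, row, xout = xNew)$y))
    out[, , v] <- apply(fx, 2L, function(col) stats::approx(g$y, col, xout = yNew)$y)
  }
  geomNew <- new("DisplayGeometry", widthDeg = geom@widthDeg,
                 heightDeg = geom@heightDeg, gridNx = nxNew, gridNy = nyNew,
                 trS = geom@trS)
  new("StimulusMovie", frames = out, geometry = geomNew,
      flickerTrack = movie@flickerTrack)
}

# ---- internal: lattice evaluation ----

# Evaluate the OLS-profiled RSS on a lattice of (x, y, sigma) x omega given a
# model context. Returns the best lattice point (ties broken by smallest
# sigma, then smallest |x| + |y|).
.latticeBest <- function(ctx, obs, xs, ys, sigmas, omegas) {
  spatial <- expand.grid(x0 = xs, y0 = ys, sigma = sigmas,
                         KEEP.OUT.ATTRS = FALSE)
  G <- exp(-(outer(ctx$pixX, spatial$x0, "-")^2 +
             outer(ctx$pixY, spatial$y0, "-")^2) /
           matrix(2 * spatial$sigma^2, nrow = length(ctx$pixX),
                  ncol = nrow(spatial), byrow = TRUE))
  S <- (ctx$frames %*% G) * ctx$cellArea       # nVol x nSpatial
  om <- mean(obs)
  co <- obs - om
  best <- NULL
  for (w in omegas) {
    mix <- w * ctx$gS + (1 - w) * ctx$gT
    B <- .causalConv(S * mix, ctx$hrf)          # nVol x nSpatial
    pm <- colMeans(B)
    Bc <- sweep(B, 2L, pm)
    vp <- colSums(Bc^2)
    cv <- as.numeric(crossprod(Bc, co))
    beta <- ifelse(vp < 1e-300, 0, cv / vp)
    rssCol <- sum(co^2) - beta^2 * vp
    cand <- data.frame(spatial, omega = w, beta = beta,
                       mu = om - beta * pm, rss = rssCol)
    best <- rbind(best, cand[order(cand$rss, cand$sigma,
                                   abs(cand$x0) + abs(cand$y0)), ][1L, ])
  }
  best[order(best$rss, best$sigma, abs(best$x0) + abs(best$y0)), ][1L, ]
}

# step sizes of a lattice (for adaptive shrinking)
.latStep <- function(v) if (length(v) > 1L) diff(v)[1] else 0

#' Coarse adaptive grid search (phase 1)
#'
#' Evaluates the model on a sparse lattice over `(x0, y0, sigma, omega)`
#' (sigma log-spaced), solving `beta` and `mu` in closed form per lattice
#' point by ordinary least squares of the unit-amplitude prediction against
#' the data. After each pass the search bounds shrink to the one-cell
#' neighborhood of the incumbent and the lattice is re-laid at the same
#' density (`space@passes` passes in total). Ties are broken by smallest
#' sigma, then smallest `|x0| + |y0|`.
#'
#' @param obs observed time-series (finite).
#' @param movieLow the downsampled stimulus ([downsampleStimulus()]).
#' @param space a [SearchSpace-class].
#' @param globals a [GlobalParams-class].
#' @param rateHz fine channel sampling rate.
#' @return A [VoxelParams-class] seed for [simplexRefine()].
#' @export
coarseGridFit <- function(obs, movieLow, space = searchSpace(),
                          globals = globalParams(), rateHz = 480) {
  if (any(!is.finite(obs))) stop("observations must be finite")
  ctx <- .modelContext(movieLow, globals, rateHz)
  .coarseGridFitCtx(ctx, obs, space)
}

.coarseGridFitCtx <- function(ctx, obs, space) {
  b <- space@xyBoundDeg
  xs <- seq(-b, b, length.out = space@nXY)
  ys <- xs
  sigmas <- exp(seq(log(space@sigmaGridBounds[1]),
                    log(space@sigmaGridBounds[2]),
                    length.out = space@nSigma))
  omegas <- seq(0, 1, length.out = space@nOmega)
  best <- .latticeBest(ctx, obs, xs, ys, sigmas, omegas)
  if (space@passes > 1L) {
    for (p in seq_len(space@passes - 1L)) {
      dx <- .latStep(xs); dl <- .latStep(log(sigmas)); dw <- .latStep(omegas)
      xs <- seq(max(-b, best$x0 - dx), min(b, best$x0 + dx),
                length.out = space@nXY)
      ys <- seq(max(-b, best$y0 - dx), min(b, best$y0 + dx),
                length.out = space@nXY)
      sigmas <- exp(seq(max(log(space@sigmaBounds[1]), log(best$sigma) - dl),
                        min(log(space@sigmaBounds[2]), log(best$sigma) + dl),
                        length.out = space@nSigma))
      # exp(log(b)) can overshoot b by 1 ulp; keep lattice inside the bounds
      sigmas <- pmin(pmax(sigmas, space@sigmaBounds[1]), space@sigmaBounds[2])
      omegas <- seq(max(0, best$omega - dw), min(1, best$omega + dw),
                    length.out = space@nOmega)
      cand <- .latticeBest(ctx, obs, xs, ys, sigmas, omegas)
      if (cand$rss <= best$rss) best <- cand
    }
  }
  voxelParams(best$x0, best$y0, best$sigma, best$omega, best$beta, best$mu)
}

# ---- internal: simplex over the nonlinear voxel parameters ----

# Nelder-Mead over (x0, y0, sigma, omega); beta and mu enter the model
# linearly and are profiled out by OLS at every proposal, so the minimized
# objective equals the RSS minimum over all six parameters.
.refineCtx <- function(ctx, obs, seedParams, space, restarts = 1L) {
  lower <- c(-space@xyBoundDeg, -space@xyBoundDeg, space@sigmaBounds[1], 0)
  upper <- c(space@xyBoundDeg, space@xyBoundDeg, space@sigmaBounds[2], 1)
  fn <- function(p) {
    if (any(p < lower) || any(p > upper)) return(1e300)
    s <- .spatialSeries(ctx, p[1], p[2], p[3])
    pred0 <- .predictFromSpatial(ctx, s, p[4])
    .olsBetaMu(pred0, obs)[["rss"]]
  }
  p0 <- paramVector(seedParams)[1:4]
  if (any(p0 < lower) || any(p0 > upper))
    stop("seed parameters lie outside the search bounds")
  if (!is.finite(fn(p0))) stop("non-finite objective at the seed parameters")
  nIt <- 0L
  conv <- FALSE
  for (r in seq_len(restarts + 1L)) {
    opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                        control = list(maxit = 800L, reltol = 1e-12))
    p0 <- opt$par
    nIt <- nIt + opt$counts[["function"]]
    conv <- opt$convergence == 0L
  }
  s <- .spatialSeries(ctx, p0[1], p0[2], p0[3])
  ols <- .olsBetaMu(.predictFromSpatial(ctx, s, p0[4]), obs)
  prm <- voxelParams(p0[1], p0[2], p0[3], min(max(p0[4], 0), 1),
                     ols[["beta"]], ols[["mu"]])
  rssVal <- ols[["rss"]]
  new("FitResult", params = prm, rss = rssVal, r2 = .r2(rssVal, obs),
      nIterations = nIt, converged = conv)
}

#' Downhill-simplex refinement (phase 2)
#'
#' Nelder-Mead minimization of the RSS over the voxel parameters starting
#' from the coarse-grid seed, against the full-resolution stimulus. The
#' simplex walks `(x0, y0, sigma, omega)`; `beta` and `mu` enter the model
#' linearly and are solved by ordinary least squares at every proposal, so
#' the objective equals the RSS profile over all six parameters (and avoids
#' the shallow omega-beta valley a six-dimensional simplex would crawl
#' along). Out-of-bounds proposals are penalized with an effectively
#' infinite objective. The refined RSS never exceeds the seed's.
#'
#' @param obs observed time-series.
#' @param movie the full-resolution [StimulusMovie-class].
#' @param seedParams seed [VoxelParams-class] (must satisfy the bounds).
#' @param space a [SearchSpace-class].
#' @param globals a [GlobalParams-class].
#' @param rateHz fine channel sampling rate.
#' @param restarts additional simplex restarts from the incumbent (default 1).
#' @return A [FitResult-class].
#' @export
simplexRefine <- function(obs, movie, seedParams, space = searchSpace(),
                          globals = globalParams(), rateHz = 480,
                          restarts = 1L) {
  ctx <- .modelContext(movie, globals, rateHz)
  .refineCtx(ctx, obs, seedParams, space, restarts)
}

#' Two-phase fit of a single voxel
#'
#' Composition of [coarseGridFit()] on the downsampled stimulus and
#' [simplexRefine()] on the full-resolution stimulus. Deterministic given its
#' inputs.
#'
#' @param obs observed time-series.
#' @param movie full-resolution [StimulusMovie-class].
#' @param space a [SearchSpace-class].
#' @param globals a [GlobalParams-class].
#' @param movieLow optional precomputed downsampled movie.
#' @param downsampleFraction coarse-phase resolution fraction.
#' @param rateHz fine channel sampling rate.
#' @return A [FitResult-class].
#' @export
fitVoxel <- function(obs, movie, space = searchSpace(),
                     globals = globalParams(), movieLow = NULL,
                     downsampleFraction = 0.05, rateHz = 480) {
  if (any(!is.finite(obs))) stop("observations must be finite")
  if (is.null(movieLow)) movieLow <- downsampleStimulus(movie, downsampleFraction)
  ctxLow <- .modelContext(movieLow, globals, rateHz)
  ctxFull <- .modelContext(movie, globals, rateHz)
  seed <- .coarseGridFitCtx(ctxLow, obs, space)
  .refineCtx(ctxFull, obs, seed, space)
}

#' Indices of voxels surviving the variance-explained threshold
#'
#' @param fits a [PrfFitSet-class], [FitResult-class] list, or a data.frame
#'   with an `r2` column.
#' @param r2Min threshold (default 0.1).
#' @return integer vector of surviving voxel indices.
#' @export
thresholdVoxels <- function(fits, r2Min = 0.1) {
  r2 <- if (is(fits, "PrfFitSet")) fits@fits$r2
        else if (is.data.frame(fits)) fits$r2
        else vapply(fits, function(f) f@r2, numeric(1))
  which(!is.na(r2) & r2 > r2Min)
}

#' Yoked estimation of voxelwise and session-wide parameters
#'
#' Alternating (block-descent) scheme: (a) with the globals `(delta, tau)`
#' fixed, every voxel's six parameters are fitted independently (two-phase on
#' the first outer iteration, simplex-only from the incumbent thereafter);
#' (b) with all voxel parameters fixed, `(delta, log tau)` are refined by
#' Nelder-Mead to minimize the summed RSS over voxels surviving the
#' `r2 > threshold` cut. The loop stops when `|delta change| < tolDelta` and
#' `|relative tau change| < tolTauRel`, or after `maxOuter` iterations.
#' Zero-variance voxels are skipped and reported via the `skipped` column.
#'
#' @param dataset voxel-by-time numeric matrix (>= 2 voxels).
#' @param movie full-resolution [StimulusMovie-class].
#' @param space a [SearchSpace-class].
#' @param initGlobals starting [GlobalParams-class].
#' @param threshold r2 cut for the global step (default 0.1).
#' @param maxOuter maximal outer iterations (default 10).
#' @param tolDelta absolute delta tolerance (s), default 0.05.
#' @param tolTauRel relative tau tolerance, default 0.01.
#' @param downsampleFraction coarse-phase resolution fraction.
#' @param rateHz fine channel sampling rate.
#' @param verbose print outer-iteration progress.
#' @return A [PrfFitSet-class].
#' @export
fitYoked <- function(dataset, movie, space = searchSpace(),
                     initGlobals = globalParams(), threshold = 0.1,
                     maxOuter = 10L, tolDelta = 0.05, tolTauRel = 0.01,
                     downsampleFraction = 0.05, rateHz = 480,
                     verbose = FALSE) {
  dataset <- as.matrix(dataset)
  nVox <- nrow(dataset)
  if (nVox < 2L) stop("yoked fitting requires at least 2 voxels")
  skipped <- apply(dataset, 1L, function(y) stats::var(y) <= 0 || any(!is.finite(y)))
  if (all(skipped)) stop("no voxel has usable variance")
  movieLow <- downsampleStimulus(movie, downsampleFraction)

  globals <- initGlobals
  fits <- vector("list", nVox)
  trace <- data.frame(iteration = integer(), delta = numeric(),
                      tau = numeric(), rss = numeric())
  converged <- FALSE

  for (outer in seq_len(maxOuter)) {
    ctxLow <- .modelContext(movieLow, globals, rateHz)
    ctxFull <- .modelContext(movie, globals, rateHz)
    for (v in which(!skipped)) {
      seed <- if (outer == 1L) .coarseGridFitCtx(ctxLow, dataset[v, ], space)
              else fits[[v]]@params
      fits[[v]] <- .refineCtx(ctxFull, dataset[v, ], seed, space,
                              restarts = if (outer == 1L) 1L else 0L)
    }
    surv <- intersect(thresholdVoxels(fits[!skipped][], threshold),
                      seq_len(sum(!skipped)))
    survIdx <- which(!skipped)[surv]
    if (!length(survIdx))
      stop("no voxel exceeds r2 > ", threshold,
           " at the global step; lower the threshold")

    # (b) refine (delta, log tau) with voxel spatial parameters fixed.
    # Given (x0, y0, sigma) the prediction is linear in (omega*beta,
    # (1-omega)*beta, mu), so those are re-solved per voxel in closed form
    # inside the objective: same fixed point as holding them fixed, but the
    # alternation is not throttled by the omega-tau degeneracy.
    S <- vapply(survIdx, function(v)
      .spatialSeries(ctxFull, fits[[v]]@params@x0, fits[[v]]@params@y0,
                     fits[[v]]@params@sigma), numeric(ctxFull$nVol))
    obsM <- dataset[survIdx, , drop = FALSE]
    gfn <- function(p) {
      if (abs(p[1]) > 3) return(1e300)
      gl <- globalParams(p[1], exp(p[2]))
      gains <- .volumeGains(ctxFull$track, gl, ctxFull$trS, rateHz)
      hrf <- doubleGammaHrf(gl@delta, ctxFull$trS)@samples
      BS <- .causalConv(S * gains[, "gS"], hrf)
      BT <- .causalConv(S * gains[, "gT"], hrf)
      tot <- 0
      for (j in seq_along(survIdx))
        tot <- tot + .olsChannels(BS[, j], BT[, j], obsM[j, ])$rss
      tot
    }
    p0 <- c(globals@delta, log(globals@tau))
    gopt <- stats::optim(p0, gfn, method = "Nelder-Mead",
                         control = list(maxit = 400L, reltol = 1e-10))
    newGlobals <- if (gopt$value <= gfn(p0))
      globalParams(gopt$par[1], exp(gopt$par[2])) else globals
    trace <- rbind(trace, data.frame(
      iteration = outer, delta = newGlobals@delta, tau = newGlobals@tau,
      rss = min(gopt$value, gfn(p0))))
    if (verbose)
      message(sprintf("outer %d: delta=%.4g tau=%.4g rss=%.6g", outer,
                      newGlobals@delta, newGlobals@tau, trace$rss[outer]))
    dDelta <- abs(newGlobals@delta - globals@delta)
    dTau <- abs(newGlobals@tau - globals@tau) / globals@tau
    globals <- newGlobals
    if (outer > 1L && dDelta < tolDelta && dTau < tolTauRel) {
      converged <- TRUE
      break
    }
  }

  # final voxel pass under the converged globals
  ctxFull <- .modelContext(movie, globals, rateHz)
  for (v in which(!skipped))
    fits[[v]] <- .refineCtx(ctxFull, dataset[v, ], fits[[v]]@params, space,
                            restarts = 0L)

  tab <- do.call(rbind, lapply(seq_len(nVox), function(v) {
    if (skipped[v])
      return(data.frame(x0 = NA_real_, y0 = NA_real_, sigma = NA_real_,
                        omega = NA_real_, beta = NA_real_, mu = NA_real_,
                        rss = NA_real_, r2 = NA_real_, converged = NA,
                        skipped = TRUE))
    f <- fits[[v]]
    data.frame(x0 = f@params@x0, y0 = f@params@y0, sigma = f@params@sigma,
               omega = f@params@omega, beta = f@params@beta, mu = f@params@mu,
               rss = f@rss, r2 = f@r2, converged = f@converged,
               skipped = FALSE)
  }))
  rownames(tab) <- rownames(dataset)
  new("PrfFitSet", fits = tab, globals = globals, trace = trace,
      converged = converged)
}
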