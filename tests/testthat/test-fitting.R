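test_that("rss matches hand arithmetic", {
  expect_equal(rss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rss(rep(0, 5), rep(2, 5)), 5 * 4)   # obs = pred + c
  expect_equal(rss(c(1, 1, 1), c(1, 2, 3)), 5)
  expect_error(rss(1:3, 1:4), "equal length")
})

test_that("stimulus downsampling preserves extent, constants and mass", {
  expect_identical(downsampleStimulus(tinyBar, 1), tinyBar)
  low <- downsampleStimulus(midBar, 0.3)
  expect_equal(movieGeometry(low)@widthDeg, movieGeometry(midBar)@widthDeg)
  expect_equal(nVolumes(low), nVolumes(midBar))
  # constant frames stay constant under bilinear interpolation
  const <- new("StimulusMovie",
               frames = array(0.5, dim = c(21, 21, 2)), geometry = tinyGeom,
               flickerTrack = c(10, 10))
  expect_true(all(abs(frames(downsampleStimulus(const, 0.6)) - 0.5) < 1e-12))
  # bar mass (on-fraction) preserved within 10%
  expect_equal(mean(frames(low)), mean(frames(midBar)), tolerance = 0.1)
  expect_error(downsampleStimulus(tinyBar, 0), "fraction")
  expect_error(downsampleStimulus(tinyBar, 1.5), "fraction")
})

test_that("coarse grid search equals exhaustive enumeration on a frozen lattice", {
  gl <- defaultGlobals
  movLow <- tinyBarLow
  space5 <- searchSpace(nXY = 5L, nSigma = 5L, nOmega = 5L, passes = 1L)
  # oracle: enumerate the same lattice with exported primitives
  xs <- seq(-10, 10, length.out = 5)
  sigmas <- exp(seq(log(0.25), log(8), length.out = 5))
  omegas <- seq(0, 1, length.out = 5)
  geomLow <- movieGeometry(movLow)
  frLow <- frames(movLow)
  gains <- channelGains(renderFlickerWaveform(flickerTrack(movLow), 1.5, 480),
                        gl, 1.5)
  hrf <- doubleGammaHrf(gl@delta, 1.5)@samples
  conv <- function(x) {
    y <- stats::convolve(c(x, rep(0, length(hrf))), rev(hrf), type = "open")
    y[seq_along(x)]
  }
  lattice <- expand.grid(x0 = xs, y0 = xs, sigma = sigmas, omega = omegas,
                         KEEP.OUT.ATTRS = FALSE)
  preds <- vapply(seq_len(nrow(lattice)), function(i) {
    G <- spatialRF(lattice$x0[i], lattice$y0[i], lattice$sigma[i], geomLow)
    s <- vapply(seq_len(dim(frLow)[3]),
                function(v) sum(frLow[, , v] * G), numeric(1)) *
      gridSpacing(geomLow)^2
    conv(s * (lattice$omega[i] * gains[, "gS"] +
              (1 - lattice$omega[i]) * gains[, "gT"]))
  }, numeric(nVolumes(movLow)))

  oracleFit <- function(obs) {
    ols <- apply(preds, 2L, function(p) {
      b <- stats::coef(stats::lm(obs ~ p))
      sum((obs - b[1] - b[2] * p)^2)
    })
    cand <- cbind(lattice, rss = ols)
    cand[order(cand$rss, cand$sigma, abs(cand$x0) + abs(cand$y0)), ][1L, ]
  }

  set.seed(42)
  for (i in 1:3) {
    truth <- voxelParams(sample(xs, 1), sample(xs, 1), sample(sigmas, 1),
                         omega = sample(omegas, 1), beta = 2, mu = 50)
    obs <- predictBold(tinyBar, truth, gl) + rnorm(200, 0, 0.5)
    got <- coarseGridFit(obs, movLow, space5, gl)
    want <- oracleFit(obs)
    expect_equal(got@x0, want$x0)
    expect_equal(got@y0, want$y0)
    expect_equal(got@sigma, want$sigma)
    expect_equal(got@omega, want$omega)
  }
})

test_that("coarse grid recovers lattice-point voxels exactly and flat data trivially", {
  gl <- defaultGlobals
  truth <- voxelParams(-5, 5, exp(mean(log(c(0.25, 8)))), omega = 0.5,
                       beta = 3, mu = 10)
  obs <- predictBold(tinyBar, truth, gl)
  space5 <- searchSpace(nXY = 5L, nSigma = 5L, nOmega = 5L, passes = 1L)
  seed <- coarseGridFit(obs, tinyBarLow, space5, gl)
  expect_equal(seed@x0, -5); expect_equal(seed@y0, 5)
  expect_equal(seed@omega, 0.5)

  flat <- coarseGridFit(rep(4, 200), tinyBarLow, space5, gl)
  expect_equal(flat@beta, 0, tolerance = 1e-9)
  expect_equal(flat@mu, 4, tolerance = 1e-9)
  expect_error(coarseGridFit(rep(NA_real_, 200), tinyBarLow, space5, gl),
               "finite")
})

test_that("simplex refinement descends and recovers noiseless parameters", {
  gl <- globalParams(delta = 0.4, tau = 2.5e-5)
  truth <- voxelParams(3.4, -2.2, 1.3, omega = 0.65, beta = 2.1, mu = 100)
  obs <- noiselessSeries(truth, tinyConcat, gl)
  seed <- voxelParams(3.4 * 1.1, -2.2 * 1.1, 1.3 * 1.1, omega = 0.6,
                      beta = 1.9, mu = 99)
  fit <- simplexRefine(obs, tinyConcat, seed, searchSpace(), gl)
  expect_lte(fit@rss, rss(predictBold(tinyConcat, seed, gl), obs))
  p <- paramVector(fit@params)
  expect_lt(abs(p["x0"] - 3.4), 0.1)
  expect_lt(abs(p["y0"] + 2.2), 0.1)
  expect_lt(abs(p["sigma"] - 1.3), 0.1)
  expect_lt(abs(p["omega"] - 0.65), 0.02)
  expect_gt(fit@r2, 0.999)
  badSeed <- voxelParams(50, 0, 1)   # outside the spatial bounds
  expect_error(simplexRefine(obs, tinyConcat, badSeed, searchSpace(), gl),
               "bounds")
})

test_that("two-phase voxel fits are deterministic, bounded-omega-safe and noise-calibrated", {
  gl <- defaultGlobals
  # omega planted at both bounds is recovered without clipping artifacts
  for (om in c(0, 1)) {
    truth <- voxelParams(-4, 3, 2, omega = om, beta = 1.5, mu = 50)
    f <- fitVoxel(noiselessSeries(truth), tinyConcat, tinySpace, gl,
                  movieLow = tinyConcatLow)
    expect_equal(f@params@omega, om, tolerance = 1e-6)
    expect_gt(f@r2, 0.999)
  }
  # duplicate voxel -> identical result
  truth <- voxelParams(2, 2, 1.5, omega = 0.4, beta = 2, mu = 10)
  obs <- noiselessSeries(truth) + withSeed(1, rnorm(nVolumes(tinyConcat)))
  f1 <- fitVoxel(obs, tinyConcat, tinySpace, gl, movieLow = tinyConcatLow)
  f2 <- fitVoxel(obs, tinyConcat, tinySpace, gl, movieLow = tinyConcatLow)
  expect_identical(paramVector(f1@params), paramVector(f2@params))
  # pure-noise voxels stay below the activation threshold (median)
  r2s <- vapply(1:15, function(s) {
    y <- withSeed(100 + s, rnorm(nVolumes(tinyBar)))
    fitVoxel(y, tinyBar, tinySpace, gl, movieLow = tinyBarLow)@r2
  }, numeric(1))
  expect_lt(median(r2s), 0.1)
})

test_that("r2 decreases monotonically with added noise variance", {
  gl <- defaultGlobals
  truth <- voxelParams(1, -3, 1.8, omega = 0.7, beta = 2, mu = 100)
  clean <- noiselessSeries(truth, tinyBar, gl)
  sds <- stats::sd(clean) / c(8, 2, 0.5)   # SNR 8, 2, 0.5
  r2s <- vapply(seq_along(sds), function(i) {
    y <- clean + withSeed(7L, rnorm(length(clean), 0, sds[i]))
    fitVoxel(y, tinyBar, tinySpace, gl, movieLow = tinyBarLow)@r2
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("threshold selection returns exactly the suprathreshold voxels", {
  tab <- data.frame(r2 = c(0, 0.05, 0.1, 0.11, 0.9, NA))
  expect_equal(thresholdVoxels(tab), c(4L, 5L))
  expect_equal(thresholdVoxels(data.frame(r2 = rep(0, 3))), integer(0))
  expect_equal(thresholdVoxels(data.frame(r2 = rep(1, 3))), 1:3)
  expect_equal(thresholdVoxels(tab, r2Min = 0.5), 5L)
})

test_that("yoked fitting recovers shared globals and descends monotonically", {
  cfg <- phantomConfig(voxelSizeMm = 2.8, delta = 0.3, tau = 2.8e-5)
  ph <- makePhantom(cfg)
  se <- simulateRuns(ph, tinyConcat, noise = list(sd = 0), nRuns = 1L,
                     seed = 3L, discardFirst = 0L)
  Y <- SummarizedExperiment::assay(se, 1L)
  fit <- fitYoked(Y, tinyConcat, tinySpace,
                  initGlobals = globalParams(0, 2e-5), maxOuter = 6L)
  expect_true(fit@converged)
  expect_lt(abs(fitGlobals(fit)@delta - 0.3), 0.05)
  expect_lt(abs(fitGlobals(fit)@tau - 2.8e-5) / 2.8e-5, 0.05)
  tr <- truthParams(ph)
  ft <- fitTable(fit)
  expect_lt(max(abs(ft$x0 - tr$x0)), 0.1)
  expect_lt(max(abs(ft$omega - tr$omega)), 0.02)
  expect_true(all(ft$r2 > 0.999))
  # block-descent: summed suprathreshold RSS non-increasing across outers
  expect_true(all(diff(fit@trace$rss) <= 1e-6 * fit@trace$rss[1]))

  # zero-variance voxels are skipped and reported
  Y2 <- rbind(Y[1:3, ], rep(5, ncol(Y)))
  fit2 <- fitYoked(Y2, tinyConcat, tinySpace,
                   initGlobals = globalParams(0.3, 2.8e-5), maxOuter = 2L)
  expect_true(fitTable(fit2)$skipped[4])
  expect_true(is.na(fitTable(fit2)$r2[4]))

  # no suprathreshold voxel is an explicit error
  noise <- matrix(withSeed(2, rnorm(3 * nVolumes(tinyConcat))), nrow = 3)
  expect_error(fitYoked(noise, tinyConcat, tinySpace, threshold = 0.9,
                        maxOuter = 2L), "threshold")
})

test_that("voxel fits move smoothly with small changes in the yoked globals", {
  truth <- voxelParams(2.5, -1.5, 1.2, omega = 0.6, beta = 2, mu = 100)
  g1 <- globalParams(0, 2e-5)
  g2 <- globalParams(0.08, 2e-5 * 1.04)   # delta +0.08 s, tau +4%
  obs <- noiselessSeries(truth, tinyConcat, g1)
  f1 <- fitVoxel(obs, tinyConcat, tinySpace, g1, movieLow = tinyConcatLow)
  f2 <- fitVoxel(obs, tinyConcat, tinySpace, g2, movieLow = tinyConcatLow)
  expect_lt(abs(f1@params@x0 - f2@params@x0), 0.1)
  expect_lt(abs(f1@params@y0 - f2@params@y0), 0.1)
  expect_lt(abs(f1@params@sigma - f2@params@sigma), 0.1)
})
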