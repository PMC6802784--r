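test_that("spatial receptive field matches the Gaussian closed form", {
  g <- spatialRF(0, 0, 2, tinyGeom)
  expect_equal(g[11, 11], 1)                     # fixation grid point
  expect_equal(g[11, 13], exp(-1 / 2))           # 2 deg = one sigma away
  # isotropy: equal values at equal radii
  expect_equal(g[11, 13], g[13, 11], tolerance = 1e-12)
  expect_equal(g[11, 9], g[9, 11], tolerance = 1e-12)
  expect_error(spatialRF(0, 0, -1, tinyGeom), "positive")
})

test_that("sustained kernel is a unit-area Gaussian with the printed width", {
  tau <- 5e-4
  ks <- sustainedKernel(globalParams(tau = tau), trS = 1.5, rateHz = 480)
  s <- ks@samples
  n <- length(s)
  expect_equal(s, rev(s), tolerance = 1e-12)     # symmetric about t0
  expect_equal(sum(s) / 480, 1, tolerance = 1e-9)
  # FWHM of the shape: 2 * sqrt(2 * pi * tau * log(2))
  t <- seq(0, 1.5, length.out = n)
  half <- max(s) / 2
  above <- range(which(s >= half))
  # linear interpolation of the crossings
  crossL <- stats::approx(s[c(above[1] - 1, above[1])],
                          t[c(above[1] - 1, above[1])], xout = half)$y
  crossR <- stats::approx(s[c(above[2], above[2] + 1)],
                          t[c(above[2], above[2] + 1)], xout = half)$y
  expect_equal(crossR - crossL, 2 * sqrt(2 * pi * tau * log(2)),
               tolerance = 0.02)
  expect_error(sustainedKernel(globalParams(tau = 1e-9 - 1e-9)), "positive")
})

test_that("transient kernel is the antisymmetric derivative with extrema at t0 +/- sqrt(pi tau)", {
  tau <- 5e-4
  ks <- sustainedKernel(globalParams(tau = tau), 1.5, 480)
  kt <- transientKernel(ks)
  d <- kt@samples
  expect_lt(abs(sum(d)), 1e-8 * max(abs(d)) * length(d))
  expect_equal(d, -rev(d), tolerance = 1e-9)     # antisymmetric
  t <- seq(0, 1.5, length.out = length(d))
  expect_equal(d[which.min(abs(t - ks@t0))], 0, tolerance = 1e-6 * max(abs(d)))
  expect_equal(t[which.max(d)], ks@t0 - sqrt(pi * tau), tolerance = 2 / 480)
  expect_equal(t[which.min(d)], ks@t0 + sqrt(pi * tau), tolerance = 2 / 480)
})

test_that("double-gamma HRF peaks at 5 s plus the delay, with a modest undershoot", {
  h0 <- doubleGammaHrf(0, trS = 0.01)
  t <- seq(0, 32, by = 0.01)
  expect_equal(t[which.max(h0@samples)], 5, tolerance = 0.011 / 5)
  h1 <- doubleGammaHrf(1, trS = 0.01)
  expect_equal(t[which.max(h1@samples)] - t[which.max(h0@samples)], 1,
               tolerance = 0.021)
  expect_lt(min(h0@samples), 0)
  expect_lt(abs(min(h0@samples)), 0.3 * max(h0@samples))
  expect_error(doubleGammaHrf(5), "\\[-3, 3\\]")
})

test_that("channel gains reproduce the sustained/transient frequency tuning", {
  gl <- defaultGlobals
  expect_true(all(channelGains(renderFlickerWaveform(c(0, 0), 1.5, 480),
                               gl, 1.5) == 0))
  fs <- seq(2, 60, by = 2)   # even: whole flicker cycles per volume
  g <- t(vapply(fs, function(f)
    channelGains(renderFlickerWaveform(f, 1.5, 480), gl, 1.5)[1, ],
    numeric(2)))
  expect_true(all(diff(g[, 1]) < 0))            # sustained low-pass
  peak <- which.max(g[, 2])                     # transient band-pass
  expect_gt(peak, 1); expect_lt(peak, length(fs))
  expect_gt(g[fs == 10, 1], g[fs == 20, 1])
  expect_gt(g[fs == 20, 2], g[fs == 10, 2])
  expect_true(all(g >= 0))
})

test_that("sustained gain ratios match the kernel's FFT transfer oracle", {
  gl <- defaultGlobals
  ks <- sustainedKernel(gl, 1.5, 480)
  # zero-padded FFT of the kernel: attenuation at 0.1 Hz resolution
  pad <- c(ks@samples / 480, rep(0, 4800 - length(ks@samples)))
  att <- Mod(stats::fft(pad))
  freqs <- (seq_along(att) - 1) * 480 / 4800
  fs <- c(4, 10, 20, 40)
  gains <- vapply(fs, function(f)
    channelGains(renderFlickerWaveform(f, 1.5, 480), gl, 1.5)[1, "gS"],
    numeric(1))
  oracle <- att[match(fs, freqs)]
  for (i in 2:length(fs))
    expect_equal(gains[i] / gains[1], oracle[i] / oracle[1], tolerance = 0.05)
})

test_that("BOLD predictions are linear in beta and gated by omega", {
  gl <- defaultGlobals
  p0 <- voxelParams(2, -1, 1.5, omega = 0.6, beta = 0, mu = 7)
  expect_equal(predictBold(tinyBar, p0, gl), rep(7, 200))

  p1 <- voxelParams(2, -1, 1.5, omega = 0.6, beta = 1, mu = 7)
  p2 <- voxelParams(2, -1, 1.5, omega = 0.6, beta = 2, mu = 7)
  y1 <- predictBold(tinyBar, p1, gl)
  y2 <- predictBold(tinyBar, p2, gl)
  expect_equal(y2 - 7, 2 * (y1 - 7), tolerance = 1e-9)

  # omega = 1 uses only the sustained channel (oracle: independent
  # composition from exported primitives with the transient gain zeroed)
  gains <- channelGains(renderFlickerWaveform(flickerTrack(tinyBar), 1.5, 480),
                        gl, 1.5)
  G <- spatialRF(2, -1, 1.5, tinyGeom)
  fr <- frames(tinyBar)
  s <- vapply(seq_len(dim(fr)[3]),
              function(i) sum(fr[, , i] * G) * gridSpacing(tinyGeom)^2,
              numeric(1))
  hrf <- doubleGammaHrf(gl@delta, 1.5)@samples
  conv <- function(x) {
    y <- stats::convolve(c(x, rep(0, length(hrf))), rev(hrf), type = "open")
    y[seq_along(x)]
  }
  for (om in c(0, 1)) {
    manual <- 7 + conv(s * (om * gains[, "gS"] + (1 - om) * gains[, "gT"]))
    got <- predictBold(tinyBar, voxelParams(2, -1, 1.5, omega = om,
                                            beta = 1, mu = 7), gl)
    expect_equal(got, manual, tolerance = 1e-8)
  }
})

test_that("sustained- and transient-rich voxels show the opposite pass-amplitude modulation", {
  gl <- defaultGlobals
  peakBy <- function(om) {
    y <- predictBold(tinyBar, voxelParams(0, 0, 2, omega = om, beta = 1,
                                          mu = 0), gl)
    c(hz10 = max(y[1:100]), hz20 = max(y[101:200]))
  }
  sus <- peakBy(0.83)
  tra <- peakBy(0.17)
  expect_gt(sus["hz10"], sus["hz20"])   # attenuation at 20 Hz
  expect_gt(tra["hz20"], tra["hz10"])   # reversed for transient-rich
})

test_that("predictions are invariant to grid refinement within 1%", {
  gl <- defaultGlobals
  p <- voxelParams(3, 2, 1.5, omega = 0.7, beta = 1, mu = 0)
  # doubling the default grid density (0.25 -> 0.125 deg)
  y1 <- predictBold(makeBarStimulus(), p, gl)
  y2 <- predictBold(makeBarStimulus(fieldGeometry(spacingDeg = 0.125)),
                    p, gl)
  expect_lt(sqrt(sum((y2 - y1)^2) / sum(y2^2)), 0.01)
})
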