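#' Sustained temporal channel kernel
#'
#' The sustained channel is a one-dimensional Gaussian in time spanning one
#' volume acquisition, centered at `t0 = trS / 2`, with the exponent
#' `-(t - t0)^2 / (2 * pi * tau)` (so the effective Gaussian SD is
#' `sqrt(pi * tau)` seconds; `tau` is a reparameterized dispersion with no
#' physiological meaning attached). The kernel is normalized to unit area so
#' that channel output amplitudes are commensurable across `tau`; this pins
#' down the amplitude degeneracy between `tau` and the mixing weight `omega`
#' up to the yoking scheme.
#'
#' @param globals a [GlobalParams-class] (uses `tau`).
#' @param trS volume duration (s).
#' @param rateHz fine sampling rate (Hz).
#' @return A [TemporalKernel-class] sampled on `seq(0, trS, by = 1/rateHz)`
#'   (odd length, exact center).
#' @export
sustainedKernel <- function(globals, trS = 1.5, rateHz = 480) {
  if (globals@tau <= 0) stop("tau must be positive")
  n <- round(trS * rateHz)
  if (abs(n - trS * rateHz) > 1e-9)
    stop("trS * rateHz must be a whole number of samples")
  t <- seq(0, trS, length.out = n + 1L)
  t0 <- trS / 2
  s <- exp(-(t - t0)^2 / (2 * pi * globals@tau))
  s <- s / (sum(s) / rateHz)  # unit area
  new("TemporalKernel", samples = s, rateHz = rateHz, t0 = t0)
}

#' Transient temporal channel kernel
#'
#' The transient channel is the first derivative of the sustained kernel,
#' computed by central differences on the same grid (one-sided at the ends).
#' It is antisymmetric about the kernel center and sums to (numerically)
#' zero.
#'
#' The derivative is additionally scaled by `1 / (2 * pi * balanceHz)` so
#' that both channels produce the same rectified output for a sinusoid at
#' `balanceHz` (default 15 Hz, the midpoint of the bar stimulus's two
#' flicker frequencies). A raw derivative's rectified response to a
#' sinusoid at frequency `f` is exactly `2 * pi * f` times the sustained
#' response, which makes the mixture weight practically unidentifiable at
#' realistic noise levels (every mixture is transient-dominated); the
#' channel amplitudes are only defined by the model up to this
#' normalization, just as the dispersion carries no physiological meaning.
#' The scaling is a monotone reparameterization of the weight and leaves
#' the kernel's shape, zero-sum, antisymmetry and extrema untouched.
#'
#' @param sustained a sustained-channel [TemporalKernel-class].
#' @param balanceHz frequency (Hz) at which the two channels have equal
#'   rectified gain.
#' @return A [TemporalKernel-class] on the same grid.
#' @export
transientKernel <- function(sustained, balanceHz = 15) {
  s <- sustained@samples
  n <- length(s)
  if (n < 3L) stop("sustained kernel must have at least 3 samples")
  dt <- 1 / sustained@rateHz
  d <- numeric(n)
  d[1] <- (s[2] - s[1]) / dt
  d[n] <- (s[n] - s[n - 1]) / dt
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  new("TemporalKernel", samples = d / (2 * pi * balanceHz),
      rateHz = sustained@rateHz, t0 = sustained@t0)
}

#' Double-gamma hemodynamic response function
#'
#' The canonical two-gamma HRF: a response gamma peaking at `5 + delta`
#' seconds minus an undershoot gamma peaking at `15 + delta` seconds scaled
#' by 1/6 (gamma scale 1 s, shapes chosen so the gamma modes sit exactly at
#' those peaks). The delay `delta` therefore shifts the whole response
#' rigidly. The kernel is sampled causally over `durationS` seconds and
#' normalized to unit peak.
#'
#' @param delta delay (s), within `[-3, 3]` of the canonical 5 s peak.
#' @param trS sampling interval (s); use the TR for convolution with
#'   volume-resolution signals, or a small `dt` to inspect the shape.
#' @param durationS kernel support (s), default 32.
#' @return A [TemporalKernel-class] with `t0 = 0` (causal).
#' @export
doubleGammaHrf <- function(delta = 0, trS = 1.5, durationS = 32) {
  if (abs(delta) > 3) stop("delta must lie within [-3, 3] s of the canonical peak")
  peak1 <- 5 + delta
  peak2 <- 15 + delta
  scale <- 1
  t <- seq(0, durationS, by = trS)
  h <- stats::dgamma(t, shape = peak1 / scale + 1, scale = scale) -
    stats::dgamma(t, shape = peak2 / scale + 1, scale = scale) / 6
  h <- h / max(h)
  new("TemporalKernel", samples = h, rateHz = 1 / trS, t0 = 0)
}

#' Per-volume sustained and transient channel gains
#'
#' Convolves the fine flicker waveform with the sustained and transient
#' kernels, half-wave rectifies each channel (negative values to zero) and
#' averages within each volume, giving nonnegative per-volume gains
#' `(gS[i], gT[i])`. Kernels are applied zero-phase (centered at their
#' `t0`) and, because flicker phase resets at volume onsets, each volume is
#' convolved independently.
#'
#' @param waveform a [FineWaveform-class] whose length is a whole number of
#'   volumes.
#' @param globals a [GlobalParams-class].
#' @param trS volume duration (s).
#' @return matrix with columns `gS`, `gT`, one row per volume.
#' @export
channelGains <- function(waveform, globals, trS = 1.5) {
  rate <- waveform@rateHz
  nPer <- round(trS * rate)
  n <- length(waveform@samples)
  if (n %% nPer != 0)
    stop("waveform length is not a whole number of volumes")
  nVol <- n %/% nPer
  ks <- sustainedKernel(globals, trS, rate)
  kt <- transientKernel(ks)
  i0 <- which.min(abs(seq(0, trS, length.out = length(ks@samples)) - ks@t0))
  dt <- 1 / rate
  gs <- numeric(nVol)
  gt <- numeric(nVol)
  for (i in seq_len(nVol)) {
    seg <- waveform@samples[((i - 1L) * nPer + 1L):(i * nPer)]
    ys <- .centeredConv(seg, ks@samples * dt, i0)
    yt <- .centeredConv(seg, kt@samples * dt, i0)
    gs[i] <- mean(pmax(ys, 0))
    gt[i] <- mean(pmax(yt, 0))
  }
  cbind(gS = gs, gT = gt)
}

# Per-volume gains from a flicker track, computed once per unique frequency.
# Identical to channelGains(renderFlickerWaveform(track, ...), ...) because
# phase resets at each volume onset and kernels act volume-wise.
.volumeGains <- function(track, globals, trS = 1.5, rateHz = 480) {
  uf <- sort(unique(track))
  lut <- matrix(0, length(uf), 2L, dimnames = list(NULL, c("gS", "gT")))
  for (j in seq_along(uf)) {
    if (uf[j] > 0) {
      wf <- renderFlickerWaveform(uf[j], trS, rateHz)
      lut[j, ] <- channelGains(wf, globals, trS)
    }
  }
  idx <- match(track, uf)
  cbind(gS = lut[idx, 1L], gT = lut[idx, 2L])
}
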