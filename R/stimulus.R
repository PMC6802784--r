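#' Construct the sweeping-bar stimulus movie
#'
#' A spatially uniform bar of the given width, spanning the field along its
#' length, transits the field edge-to-edge at constant speed once per pass.
#' Direction angles give the motion direction (0 = rightward, 90 = upward,
#' 180 = leftward, 270 = downward); the bar is oriented perpendicular to its
#' motion. The bar's luminance flickers sinusoidally at the pass's frequency,
#' recorded per volume in the flicker track (0 during blank volumes).
#'
#' With the default geometry ([fieldGeometry()], a 20 deg square field), the
#' default 5 deg bar and eight passes, every interior pixel is stimulated for
#' 25% of the volumes (duty cycle 0.25).
#'
#' @param geometry a [DisplayGeometry-class]; default [fieldGeometry()].
#' @param barWidthDeg bar width (deg).
#' @param directions motion direction (deg) of each pass.
#' @param flickerHzPerPass flicker frequency (Hz) of each pass.
#' @param runDurationS total run duration (s); must divide into equal-length
#'   passes at TR resolution.
#' @param interPassBlankS blank gap between passes (s), default 0.
#' @return A [StimulusMovie-class].
#' @examples
#' mov <- makeBarStimulus(fieldGeometry(spacingDeg = 1))
#' table(flickerTrack(mov))
#' @export
makeBarStimulus <- function(geometry = fieldGeometry(),
                            barWidthDeg = 5,
                            directions = c(0, 90, 180, 270, 0, 90, 180, 270),
                            flickerHzPerPass = c(10, 10, 10, 10, 20, 20, 20, 20),
                            runDurationS = 300,
                            interPassBlankS = 0) {
  if (length(directions) != length(flickerHzPerPass))
    stop("directions and flickerHzPerPass must have the same length")
  if (barWidthDeg <= 0 || barWidthDeg > min(geometry@widthDeg, geometry@heightDeg))
    stop("bar width must be positive and no larger than the display extent")
  if (geometry@gridNx < 2L || geometry@gridNy < 2L)
    stop("zero-area model grid")
  nPass <- length(directions)
  tr <- geometry@trS
  nVolTotal <- round(runDurationS / tr)
  if (abs(nVolTotal * tr - runDurationS) > 1e-9)
    stop("run duration must be a whole number of volumes")
  nBlank <- round(interPassBlankS / tr)
  nVolPass <- (nVolTotal - nPass * nBlank) / nPass
  if (nVolPass < 2 || abs(nVolPass - round(nVolPass)) > 1e-9)
    stop("run duration must divide into equal-length passes")
  nVolPass <- as.integer(round(nVolPass))

  g <- gridCoords(geometry)
  frames <- array(0, dim = c(geometry@gridNy, geometry@gridNx, nVolTotal))
  track <- numeric(nVolTotal)
  vol <- 0L
  for (p in seq_len(nPass)) {
    th <- directions[p] * pi / 180
    ux <- cos(th); uy <- sin(th)
    # travel extent along the motion axis: field edge to field edge
    half <- if (abs(ux) > abs(uy)) geometry@widthDeg / 2 else geometry@heightDeg / 2
    centers <- seq(-half, half, length.out = nVolPass)
    # pixel projections onto the motion axis
    proj <- outer(g$y * uy, g$x * ux, "+")
    for (i in seq_len(nVolPass)) {
      vol <- vol + 1L
      frames[, , vol] <- (abs(proj - centers[i]) <= barWidthDeg / 2) * 1
      track[vol] <- flickerHzPerPass[p]
    }
    vol <- vol + nBlank
  }
  new("StimulusMovie", frames = frames, geometry = geometry,
      flickerTrack = track)
}

#' Construct a full-field movie from a trial schedule
#'
#' Full-field stimuli are represented with an all-ones aperture so the same
#' forward model serves bar-sweep and full-field experiments; the temporal
#' information lives entirely in the flicker track. Each volume's flicker
#' frequency is the frequency of the trial active at the volume's midpoint
#' (0 if no trial covers it).
#'
#' @param schedule a [TrialSchedule-class].
#' @param geometry a [DisplayGeometry-class].
#' @param nVolumes number of volumes; default spans the schedule.
#' @return A [StimulusMovie-class].
#' @export
fullfieldMovie <- function(schedule, geometry = fieldGeometry(),
                           nVolumes = NULL) {
  tr <- geometry@trS
  tab <- schedule@trials
  if (is.null(nVolumes))
    nVolumes <- ceiling((tab$onset_s[nrow(tab)] + tab$duration_s[nrow(tab)]) / tr)
  nVolumes <- as.integer(nVolumes)
  mid <- (seq_len(nVolumes) - 0.5) * tr
  track <- numeric(nVolumes)
  for (i in seq_len(nrow(tab))) {
    on <- mid >= tab$onset_s[i] & mid < tab$onset_s[i] + tab$duration_s[i]
    track[on] <- tab$flicker_hz[i]
  }
  frames <- array(1, dim = c(geometry@gridNy, geometry@gridNx, nVolumes))
  new("StimulusMovie", frames = frames, geometry = geometry,
      flickerTrack = track)
}

#' Random full-field flicker trial schedule
#'
#' Trial durations and flicker frequencies are drawn from uniform
#' distributions (defaults 4-6 s and 2-60 Hz); trials abut one another with
#' no gaps. The same schedule is reused across runs, so the draw is fully
#' determined by `seed`.
#'
#' @param nTrials number of trials (default 75 per run).
#' @param durBoundsS uniform duration bounds (s).
#' @param freqBoundsHz uniform flicker frequency bounds (Hz).
#' @param seed integer seed; required for reproducibility across runs.
#' @return A [TrialSchedule-class].
#' @export
makeFullfieldSchedule <- function(nTrials = 75L, durBoundsS = c(4, 6),
                                  freqBoundsHz = c(2, 60), seed = 1L) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  if (any(durBoundsS <= 0) || diff(durBoundsS) < 0)
    stop("duration bounds must be positive and ordered")
  if (any(freqBoundsHz < 0) || diff(freqBoundsHz) < 0)
    stop("frequency bounds must be nonnegative and ordered")
  draws <- .withSeed(seed, list(
    dur = stats::runif(nTrials, durBoundsS[1], durBoundsS[2]),
    freq = stats::runif(nTrials, freqBoundsHz[1], freqBoundsHz[2])
  ))
  dur <- draws$dur
  freq <- draws$freq
  onset <- cumsum(c(0, dur[-nTrials]))
  new("TrialSchedule", trials = data.frame(
    onset_s = onset, duration_s = dur, flicker_hz = freq,
    sf_cpd = NA_real_, lum_offset = NA_real_))
}

#' Random full-field isoluminance trial schedule
#'
#' Red-green checkerboard trials with contrast reversal at a fixed rate.
#' Per-trial spatial frequency is log-uniform over `sfBoundsCpd`; the green
#' luminance offset is drawn continuous-uniform within
#' `+/- luminanceOffset` of the isoluminant reference point (expressed as a
#' fraction of that reference). Trial durations follow `durBoundsS`.
#'
#' @param nTrials number of trials (default 75 per run).
#' @param sfBoundsCpd spatial frequency bounds (cycles/deg), positive.
#' @param luminanceOffset maximal green-luminance offset fraction.
#' @param reversalHz contrast reversal rate (Hz) common to all trials.
#' @param durBoundsS uniform duration bounds (s).
#' @param seed integer seed.
#' @return A [TrialSchedule-class].
#' @export
makeIsoluminanceSchedule <- function(nTrials = 75L, sfBoundsCpd = c(0.1, 1),
                                     luminanceOffset = 0.05, reversalHz = 15,
                                     durBoundsS = c(4, 6), seed = 1L) {
  if (sfBoundsCpd[1] <= 0) stop("spatial frequency lower bound must be positive")
  if (nTrials < 1L) stop("nTrials must be >= 1")
  draws <- .withSeed(seed, list(
    dur = stats::runif(nTrials, durBoundsS[1], durBoundsS[2]),
    sf = exp(stats::runif(nTrials, log(sfBoundsCpd[1]), log(sfBoundsCpd[2]))),
    off = stats::runif(nTrials, -luminanceOffset, luminanceOffset)
  ))
  dur <- draws$dur
  sf <- draws$sf
  off <- draws$off
  onset <- cumsum(c(0, dur[-nTrials]))
  new("TrialSchedule", trials = data.frame(
    onset_s = onset, duration_s = dur, flicker_hz = reversalHz,
    sf_cpd = sf, lum_offset = off))
}

#' Concatenate stimulus movies in time
#'
#' Joins two movies over the same grid along the volume axis (frames and
#' flicker tracks). Useful for fitting across experiments, e.g. a bar-sweep
#' run followed by a full-field frequency sweep: with only two flicker
#' frequencies the temporal dispersion is formally unidentifiable (any tau
#' can be absorbed by the per-voxel channel amplitudes), so multi-frequency
#' data are required to pin it down.
#'
#' @param a,b [StimulusMovie-class] objects with identical geometry.
#' @return A [StimulusMovie-class] with `nVolumes(a) + nVolumes(b)` volumes.
#' @export
concatMovies <- function(a, b) {
  ga <- a@geometry; gb <- b@geometry
  if (ga@gridNx != gb@gridNx || ga@gridNy != gb@gridNy ||
      abs(ga@widthDeg - gb@widthDeg) > 1e-9 ||
      abs(ga@heightDeg - gb@heightDeg) > 1e-9 ||
      abs(ga@trS - gb@trS) > 1e-9)
    stop("movies must share the same grid geometry and TR")
  da <- dim(a@frames); db <- dim(b@frames)
  fr <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  fr[, , seq_len(da[3])] <- a@frames
  fr[, , da[3] + seq_len(db[3])] <- b@frames
  new("StimulusMovie", frames = fr, geometry = ga,
      flickerTrack = c(a@flickerTrack, b@flickerTrack))
}

#' Render the fine-time flicker waveform of a volume track
#'
#' Within each volume whose flicker frequency `f` is positive, the waveform
#' is `sin(2 * pi * f * t)` with `t` restarting at the volume onset (flicker
#' phase resets at each volume so per-volume channel gains are stationary);
#' volumes with `f = 0` are silent.
#'
#' @param track per-volume flicker frequencies (Hz), e.g.
#'   `flickerTrack(movie)`.
#' @param trS volume duration (s).
#' @param rateHz fine sampling rate; must be at least 8 times the largest
#'   frequency in `track`.
#' @return A [FineWaveform-class] with `length(track) * trS * rateHz` samples.
#' @export
renderFlickerWaveform <- function(track, trS = 1.5, rateHz = 480) {
  fmax <- if (length(track)) max(track) else 0
  if (rateHz < 8 * fmax)
    stop("sampling rate ", rateHz, " Hz violates the 8x Nyquist margin for ",
         fmax, " Hz flicker")
  nPer <- round(trS * rateHz)
  if (abs(nPer - trS * rateHz) > 1e-9)
    stop("trS * rateHz must be a whole number of samples")
  t <- (seq_len(nPer) - 1L) / rateHz
  samples <- unlist(lapply(track, function(f) {
    if (f > 0) sin(2 * pi * f * t) else numeric(nPer)
  }), use.names = FALSE)
  if (is.null(samples)) samples <- numeric(0)
  new("FineWaveform", samples = samples, rateHz = rateHz)
}
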