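test_that("bar movie encodes geometry, flicker and the design duty cycle", {
  mov <- makeBarStimulus()  # default 81x81 field, 8 passes
  fr <- frames(mov)
  expect_equal(dim(fr)[3], 200L)
  expect_true(all(fr %in% c(0, 1)))
  expect_setequal(unique(flickerTrack(mov)), c(10, 20))
  # first four passes at 10 Hz, second four at 20 Hz
  expect_equal(unique(flickerTrack(mov)[1:100]), 10)
  expect_equal(unique(flickerTrack(mov)[101:200]), 20)
  # duty cycle ~ 0.25 over the stimulated field
  expect_equal(mean(fr), 0.25, tolerance = 0.02 / 0.25)
  # every volume's aperture is a translated bar: interior volumes of a pass
  # carry the same on-pixel count up to one grid line of edge quantization
  counts <- apply(fr[, , 8:18], 3L, sum)
  expect_lte(max(counts) - min(counts), dim(fr)[1])
  # and each such frame is a contiguous vertical band (pass 1 moves in x)
  onCols <- which(colSums(fr[, , 10]) > 0)
  expect_equal(onCols, seq(min(onCols), max(onCols)))
  # interior pixels are on for ~25% of the run
  center <- fr[41, 41, ]
  expect_equal(mean(center), 0.25, tolerance = 0.15)
})

test_that("bar movie validates its configuration", {
  expect_error(makeBarStimulus(directions = c(0, 90), flickerHzPerPass = 10),
               "same length")
  expect_error(makeBarStimulus(barWidthDeg = 30), "larger than the display")
  expect_error(makeBarStimulus(tinyGeom, runDurationS = 301), "whole number")
  # full-coverage limit: a bar as wide as the field covers everything at
  # mid-pass and keeps fixation stimulated throughout
  wide <- makeBarStimulus(fieldGeometry(spacingDeg = 1), barWidthDeg = 20,
                          directions = 0, flickerHzPerPass = 10,
                          runDurationS = 31.5)   # 21 volumes: odd, center at 0
  fr <- frames(wide)
  expect_true(all(fr[, , 11] == 1))
  expect_true(all(fr[11, 11, ] == 1))
})

test_that("full-field schedules draw from the configured distributions", {
  sch <- makeFullfieldSchedule(seed = 3L)
  tab <- scheduleTable(sch)
  expect_equal(nrow(tab), 75L)
  total <- sum(tab$duration_s)
  expect_gte(total, 300); expect_lte(total, 450)
  expect_true(all(tab$flicker_hz >= 2 & tab$flicker_hz <= 60))
  # bit-reproducible under a fixed seed
  expect_identical(tab, scheduleTable(makeFullfieldSchedule(seed = 3L)))
  expect_false(identical(tab, scheduleTable(makeFullfieldSchedule(seed = 4L))))
  # Monte-Carlo mean of U(2, 60)
  big <- scheduleTable(makeFullfieldSchedule(nTrials = 1e4L, seed = 1L))
  expect_equal(mean(big$flicker_hz), 31, tolerance = 1 / 31)
  expect_error(makeFullfieldSchedule(durBoundsS = c(-1, 2)), "positive")
})

test_that("isoluminance schedules are log-uniform in spatial frequency", {
  sch <- makeIsoluminanceSchedule(seed = 5L)
  tab <- scheduleTable(sch)
  expect_true(all(abs(tab$lum_offset) <= 0.05))
  expect_true(all(tab$flicker_hz == 15))
  expect_identical(tab, scheduleTable(makeIsoluminanceSchedule(seed = 5L)))
  big <- scheduleTable(makeIsoluminanceSchedule(nTrials = 1e4L, seed = 2L))
  expect_equal(median(big$sf_cpd), sqrt(0.1 * 1), tolerance = 0.05)
  expect_error(makeIsoluminanceSchedule(sfBoundsCpd = c(0, 1)), "positive")
})

test_that("flicker waveforms are phase-locked sinusoids per volume", {
  wf0 <- renderFlickerWaveform(c(0, 0, 0), trS = 1.5, rateHz = 480)
  expect_true(all(wf0@samples == 0))
  expect_length(wf0@samples, 3 * 720)

  # one 10 Hz volume holds exactly 15 cycles: spectral peak at 10 Hz
  wf <- renderFlickerWaveform(10, trS = 1.5, rateHz = 480)
  spec <- Mod(stats::fft(wf@samples))[1:360]
  freqs <- (seq_along(spec) - 1) / 1.5
  expect_equal(freqs[which.max(spec)], 10)
  # and 30 sign changes (2 per cycle)
  expect_equal(sum(diff(sign(wf@samples[wf@samples != 0])) != 0), 29)

  wf20 <- renderFlickerWaveform(20, trS = 1.5, rateHz = 480)
  spec20 <- Mod(stats::fft(wf20@samples))[1:360]
  expect_equal(freqs[which.max(spec20)], 20)

  # waveform energy per volume is independent of frequency (integer cycles)
  en <- vapply(c(10, 20, 40), function(f)
    mean(renderFlickerWaveform(f, 1.5, 480)@samples^2), numeric(1))
  expect_true(all(abs(en - 0.5) / 0.5 < 0.01))

  expect_error(renderFlickerWaveform(80, trS = 1.5, rateHz = 480), "80")
})

test_that("full-field movies carry trial frequencies on an all-ones aperture", {
  sch <- makeFullfieldSchedule(nTrials = 10L, seed = 2L)
  mov <- fullfieldMovie(sch, tinyGeom)
  expect_true(all(frames(mov) == 1))
  tab <- scheduleTable(sch)
  mid <- (seq_len(nVolumes(mov)) - 0.5) * 1.5
  i <- 5L  # an interior volume
  tr <- which(tab$onset_s <= mid[i] & tab$onset_s + tab$duration_s > mid[i])
  expect_equal(flickerTrack(mov)[i], tab$flicker_hz[tr])
})

test_that("movies concatenate along the volume axis", {
  cc <- concatMovies(tinyBar, tinyFF)
  expect_equal(nVolumes(cc), nVolumes(tinyBar) + nVolumes(tinyFF))
  expect_equal(flickerTrack(cc),
               c(flickerTrack(tinyBar), flickerTrack(tinyFF)))
  expect_error(concatMovies(tinyBar, midBar), "geometry")
})
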