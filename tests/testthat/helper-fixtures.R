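# Shared fixtures, built once per test run. Moderate grids keep the suite
# fast while leaving the model's behavior unchanged (predictions are
# grid-invariant within 1%).

# 21 x 21 grid at 1 deg spacing, TR 1.5 s
tinyGeom <- fieldGeometry(spacingDeg = 1)
tinyBar <- makeBarStimulus(tinyGeom)
tinyBarLow <- downsampleStimulus(tinyBar)

# multi-frequency stimulus: bar sweep followed by a full-field frequency
# sweep; needed whenever tau must be identifiable
tinyFF <- fullfieldMovie(makeFullfieldSchedule(nTrials = 30L, seed = 11L),
                         tinyGeom)
tinyConcat <- concatMovies(tinyBar, tinyFF)
tinyConcatLow <- downsampleStimulus(tinyConcat)

# 41 x 41 grid versions for recovery studies
midGeom <- fieldGeometry(spacingDeg = 0.5)
midBar <- makeBarStimulus(midGeom)
midConcat <- concatMovies(midBar,
                          fullfieldMovie(makeFullfieldSchedule(nTrials = 30L,
                                                               seed = 11L),
                                         midGeom))

defaultGlobals <- globalParams()

# a small light-weight search space for unit tests
tinySpace <- searchSpace(nXY = 7L, nSigma = 5L, nOmega = 4L, passes = 2L)

# noiseless single-voxel series
noiselessSeries <- function(params, movie = tinyConcat,
                            globals = defaultGlobals) {
  predictBold(movie, params, globals)
}

# minimal CLI configuration: a few voxels, a 60 s run on a 2 deg grid
writeTinyCliConfig <- function(path, nRuns = 2L, motionSpikes = 0L,
                               noiseSd = 0.5) {
  yaml::write_yaml(list(
    stimulus = list(spacingDeg = 2, runDurationS = 120),
    phantom = list(voxelSizeMm = 2.8),
    noise = list(sd = noiseSd),
    nRuns = nRuns, motionSpikes = motionSpikes,
    fit = list(nXY = 5L, nSigma = 4L, nOmega = 3L, passes = 1L,
               maxOuter = 2L),
    bootstrap = list(sizes = c(2L, 3L), reps = 3L),
    seed = 7L
  ), path)
  path
}

expect_ari <- function(labels, truth, min = 1) {
  ari <- mclust::adjustedRandIndex(labels, truth)
  expect_gte(ari, min)
  invisible(ari)
}

withSeed <- function(seed, expr) withr::with_seed(as.integer(seed), expr)
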