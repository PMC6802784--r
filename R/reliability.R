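#' Bootstrap stability of pRF estimates versus number of runs
#'
#' For each sample size and replicate, draws that many runs without
#' replacement, averages them (with optional censoring masks and
#' initial-volume discard), refits every voxel two-phase with the globals
#' frozen at the reference fit's values, and records the absolute deviation
#' of each parameter from the all-runs reference estimate together with the
#' replicate's r2. Deviations are aggregated into a mean and a percentile
#' interval per (parameter, size).
#'
#' @param runs list of voxel-by-time run matrices (or a
#'   `SummarizedExperiment` from [simulateRuns()]).
#' @param movie full-resolution [StimulusMovie-class].
#' @param sizes run sample sizes (each < number of runs, except the
#'   degenerate all-runs size which is allowed for testing).
#' @param reps replicates per size (default 200).
#' @param seed integer seed.
#' @param space a [SearchSpace-class].
#' @param globals reference [GlobalParams-class] (frozen during refits); when
#'   `NULL` they are taken from the reference fit metadata if available, else
#'   default.
#' @param reference optional precomputed all-runs reference [PrfFitSet-class];
#'   computed by [fitYoked()] when `NULL` and `globals` is `NULL`, else by
#'   frozen-globals voxel fits.
#' @param masks per-run censor masks (optional).
#' @param discardFirst initial volumes to drop (default 0 for matrices
#'   already aligned to the stimulus; use 4 for raw simulated runs).
#' @param downsampleFraction coarse-phase resolution fraction.
#' @param interval percentile interval width (default 0.95).
#' @param rateHz fine channel sampling rate.
#' @return A [ReliabilityCurve-class].
#' @export
bootstrapStability <- function(runs, movie, sizes = 2:29, reps = 200L,
                               seed = 1L, space = searchSpace(),
                               globals = NULL, reference = NULL,
                               masks = NULL, discardFirst = 0L,
                               downsampleFraction = 0.05,
                               interval = 0.95, rateHz = 480) {
  if (is(runs, "SummarizedExperiment")) {
    if (is.null(globals)) globals <- S4Vectors::metadata(runs)$globals
    if (is.null(masks)) {
      motion <- S4Vectors::metadata(runs)$motion
      if (!is.null(motion))
        masks <- lapply(motion, function(m)
          censorVolumes(framewiseDisplacement(m)))
    }
    discardFirst <- S4Vectors::metadata(runs)$discardFirst
    runs <- as.list(SummarizedExperiment::assays(runs))
  }
  nRuns <- length(runs)
  if (any(sizes > nRuns)) stop("sample sizes cannot exceed the number of runs")
  if (is.null(globals)) globals <- globalParams()
  movieLow <- downsampleStimulus(movie, downsampleFraction)
  ctxLow <- .modelContext(movieLow, globals, rateHz)
  ctxFull <- .modelContext(movie, globals, rateHz)
  parNames <- c("x0", "y0", "sigma", "omega", "beta", "mu")

  fitMatrix <- function(Y) {
    t(apply(Y, 1L, function(y) {
      seedP <- .coarseGridFitCtx(ctxLow, y, space)
      f <- .refineCtx(ctxFull, y, seedP, space)
      c(paramVector(f@params), r2 = f@r2)
    }))
  }

  refY <- meanRun(runs, masks, discardFirst)
  refTab <- if (!is.null(reference)) {
    stopifnot(is(reference, "PrfFitSet"))
    cbind(as.matrix(reference@fits[, parNames]), r2 = reference@fits$r2)
  } else fitMatrix(refY)
  nVox <- nrow(refTab)

  # draw order within a subset is irrelevant; sorting canonicalizes the
  # run average (so drawing all runs reproduces the reference bit-exactly)
  drawSets <- .withSeed(seed, {
    lapply(sizes, function(sz)
      lapply(seq_len(reps), function(r) sort(sample.int(nRuns, sz))))
  })

  long <- vector("list", length(sizes) * reps)
  i <- 0L
  for (si in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      idx <- drawSets[[si]][[r]]
      Y <- meanRun(runs[idx], if (is.null(masks)) NULL else masks[idx],
                   discardFirst)
      tab <- fitMatrix(Y)
      dev <- abs(tab[, parNames, drop = FALSE] -
                 refTab[, parNames, drop = FALSE])
      i <- i + 1L
      long[[i]] <- data.frame(
        parameter = rep(c(parNames, "r2"), each = nVox),
        size = sizes[si], replicate = r, voxel = seq_len(nVox),
        deviation = c(as.numeric(dev), rep(NA_real_, nVox)),
        value = c(as.numeric(tab[, parNames]), tab[, "r2"]))
    }
  }
  long <- do.call(rbind, long)

  alpha <- (1 - interval) / 2
  summ <- do.call(rbind, lapply(split(
    long[long$parameter != "r2", ],
    list(long$parameter[long$parameter != "r2"],
         long$size[long$parameter != "r2"]), drop = TRUE),
    function(d) data.frame(
      parameter = d$parameter[1], size = d$size[1],
      mean_abs_dev = mean(d$deviation),
      lo = stats::quantile(d$deviation, alpha, names = FALSE),
      hi = stats::quantile(d$deviation, 1 - alpha, names = FALSE),
      reps = length(unique(d$replicate)))))
  rownames(summ) <- NULL
  new("ReliabilityCurve", summary = summ, long = long,
      reference = as.data.frame(refTab))
}
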