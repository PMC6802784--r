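#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Framewise displacement from rigid motion parameters
#'
#' The framewise displacement aggregates the volume-to-volume change of the
#' six rigid-body motion-correction parameters:
#' `FD[i] = sum(|diff translations|) + r * sum(|diff rotations|)`, with
#' rotations (radians) converted to millimeters of arc on a sphere of radius
#' `headRadiusMm` (Power convention). `FD[1] = 0`.
#'
#' @param trace per-volume rigid parameters: a matrix or data.frame with 6
#'   columns (3 translations in mm, then 3 rotations in radians).
#' @param headRadiusMm head radius (mm), default 50.
#' @return numeric vector of per-volume FD (mm).
#' @export
framewiseDisplacement <- function(trace, headRadiusMm = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)")
  if (nrow(trace) < 2L) stop("at least 2 volumes are required")
  if (any(!is.finite(trace))) stop("motion parameters contain non-finite values")
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    headRadiusMm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Censor volumes by framewise displacement
#'
#' @param fd per-volume framewise displacement (mm).
#' @param thresholdMm censoring threshold; volumes with `FD > thresholdMm`
#'   are dropped (default 0.4 mm).
#' @return logical vector, `TRUE` for volumes to keep.
#' @export
censorVolumes <- function(fd, thresholdMm = 0.4) {
  fd <= thresholdMm
}

#' Average runs with volume censoring
#'
#' Discards the first `discardFirst` volumes of every run and mask, then
#' averages voxelwise and timepoint-wise over runs, excluding censored
#' volumes from the mean (per-volume exclusion, not whole-run exclusion). A
#' timepoint censored in every run is an error.
#'
#' @param runs list of voxel-by-time matrices with equal dimensions, or a
#'   `SummarizedExperiment` from [simulateRuns()] (one assay per run, masks
#'   derived from its motion traces).
#' @param masks list of per-volume logical keep masks (e.g. from
#'   [censorVolumes()]); `NULL` keeps everything.
#' @param discardFirst initial volumes to drop from each run (default 4).
#' @param ... passed to methods.
#' @return voxel-by-time matrix of censored means.
#' @export
setGeneric("meanRun", function(runs, masks = NULL, discardFirst = 4L, ...)
  standardGeneric("meanRun"))

#' @rdname meanRun
#' @export
setMethod("meanRun", "list", function(runs, masks = NULL, discardFirst = 4L, ...) {
  if (!length(runs)) stop("no runs supplied")
  runs <- lapply(runs, as.matrix)
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must have equal dimensions")
  nT <- dims[2, 1] - discardFirst
  if (nT < 1L) stop("discardFirst leaves no volumes")
  if (is.null(masks)) masks <- rep(list(rep(TRUE, dims[2, 1])), length(runs))
  if (length(masks) != length(runs))
    stop("one censor mask per run is required")
  keepIdx <- (discardFirst + 1L):dims[2, 1]
  acc <- matrix(0, dims[1, 1], nT)
  cnt <- numeric(nT)
  for (r in seq_along(runs)) {
    m <- masks[[r]]
    if (length(m) != dims[2, 1])
      stop("mask length must equal the run's volume count")
    mk <- m[keepIdx]
    y <- runs[[r]][, keepIdx, drop = FALSE]
    y[, !mk] <- 0
    acc <- acc + y
    cnt <- cnt + as.numeric(mk)
  }
  if (any(cnt == 0))
    stop("timepoint(s) censored in every run: ",
         paste(which(cnt == 0), collapse = ", "))
  sweep(acc, 2L, cnt, "/")
})

#' @rdname meanRun
#' @param thresholdMm FD censoring threshold for the SummarizedExperiment
#'   method (default 0.4 mm).
#' @export
setMethod("meanRun", "SummarizedExperiment",
  function(runs, masks = NULL, discardFirst = 4L, thresholdMm = 0.4, ...) {
    mats <- as.list(SummarizedExperiment::assays(runs))
    if (is.null(masks)) {
      motion <- S4Vectors::metadata(runs)$motion
      masks <- if (is.null(motion)) NULL
        else lapply(motion, function(m)
          censorVolumes(framewiseDisplacement(m), thresholdMm))
    }
    meanRun(mats, masks, discardFirst)
  })

#' Percent signal change conversion
#'
#' `100 * (y - mean(y)) / mean(y)` per voxel; the converted series has zero
#' mean. Matrices are converted row-wise.
#'
#' @param series numeric vector or voxel-by-time matrix with positive means.
#' @return converted vector or matrix.
#' @export
percentSignalChange <- function(series) {
  if (is.matrix(series)) {
    m <- rowMeans(series)
    if (any(m == 0)) stop("zero-mean voxel cannot be converted")
    return(100 * sweep(sweep(series, 1L, m), 1L, m, "/"))
  }
  m <- mean(series)
  if (m == 0) stop("zero-mean series cannot be converted")
  100 * (series - m) / m
}
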