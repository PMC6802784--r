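#' Write and read trial schedules as TSV
#'
#' Columns: `onset_s, duration_s, flicker_hz, sf_cpd, lum_offset`.
#'
#' @param schedule a [TrialSchedule-class].
#' @param path output file.
#' @return `writeScheduleTsv` returns `path` invisibly; `readScheduleTsv`
#'   returns a [TrialSchedule-class].
#' @export
writeScheduleTsv <- function(schedule, path) {
  utils::write.table(schedule@trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScheduleTsv
#' @export
readScheduleTsv <- function(path) {
  new("TrialSchedule",
      trials = utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Write and read 6-column motion parameter tables as TSV
#'
#' @param trace per-volume rigid parameters (3 translations mm, 3 rotations
#'   rad).
#' @param path file path.
#' @return `writeMotionTsv` returns `path` invisibly; `readMotionTsv` a
#'   numeric matrix.
#' @export
writeMotionTsv <- function(trace, path) {
  utils::write.table(as.matrix(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("trans_x", "trans_y", "trans_z",
                                   "rot_x", "rot_y", "rot_z"))
  invisible(path)
}

#' @rdname writeMotionTsv
#' @export
readMotionTsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Write a stimulus movie as NIfTI for inspection
#'
#' Stored as a `ny x nx x 1 x nVolumes` volume.
#'
#' @param movie a [StimulusMovie-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeMovieNifti <- function(movie, path) {
  d <- dim(movie@frames)
  arr <- array(movie@frames, dim = c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write a fit table as long-format TSV
#'
#' Adds derived polar angle and eccentricity columns.
#'
#' @param fitset a [PrfFitSet-class] or its fit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFitsTsv <- function(fitset, path) {
  tab <- if (is(fitset, "PrfFitSet")) fitset@fits else as.data.frame(fitset)
  pol <- cartesianToPolar(tab$x0, tab$y0)
  tab$polar_deg <- pol$polar_deg
  tab$ecc_deg <- pol$ecc_deg
  utils::write.table(cbind(voxel = seq_len(nrow(tab)), tab), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-parameter NIfTI maps on a phantom lattice
#'
#' One 3D volume per column of `values` (out-of-mask voxels are `NA`), plus
#' derived polar-angle and eccentricity maps when `x0`/`y0` are present.
#'
#' @param phantom a [Phantom-class] providing the lattice and mask.
#' @param values data.frame of per-voxel values (e.g. `fitTable(fit)` or
#'   `truthParams(phantom)`).
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return character vector of written paths, invisibly.
#' @export
writeParameterMaps <- function(phantom, values, dir, prefix = "param") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  values <- as.data.frame(values)
  if (all(c("x0", "y0") %in% names(values)) && !"polar_deg" %in% names(values)) {
    pol <- cartesianToPolar(values$x0, values$y0)
    values$polar_deg <- pol$polar_deg
    values$ecc_deg <- pol$ecc_deg
  }
  num <- names(values)[vapply(values, is.numeric, logical(1))]
  paths <- character(0)
  for (nm in num) {
    vol <- array(NA_real_, dim = phantom@dims)
    vol[phantom@maskIdx] <- values[[nm]]
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- rep(phantom@voxelSizeMm, 3L)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write simulated runs as 4D NIfTI volumes
#'
#' @param se `SummarizedExperiment` from [simulateRuns()].
#' @param phantom the generating [Phantom-class].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
writeRunsNifti <- function(se, phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in SummarizedExperiment::assayNames(se)) {
    Y <- SummarizedExperiment::assay(se, nm)
    vol <- array(NA_real_, dim = c(phantom@dims, ncol(Y)))
    nPerVol <- prod(phantom@dims)
    for (tt in seq_len(ncol(Y)))
      vol[phantom@maskIdx + (tt - 1L) * nPerVol] <- Y[, tt]
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a 4D NIfTI run into a voxel-by-time matrix
#'
#' @param path NIfTI file.
#' @param maskIdx linear indices of in-mask voxels (per 3D volume).
#' @return voxel-by-time matrix.
#' @export
readRunNifti <- function(path, maskIdx) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  nT <- if (length(d) == 4L) d[4] else 1L
  m <- matrix(arr, ncol = nT)
  m[maskIdx, , drop = FALSE]
}
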