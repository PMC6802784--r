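#' Dissimilarity of voxel time-series via their correlation profiles
#'
#' Computes the voxel-by-voxel Pearson correlation matrix `C` and returns the
#' pairwise Euclidean distances between the rows of `C`: two voxels are
#' similar when they correlate with the rest of the population in the same
#' way. The result is symmetric with a zero diagonal.
#'
#' @param ts voxel-by-time matrix (>= 3 voxels, nonzero-variance rows).
#' @return symmetric dissimilarity matrix.
#' @export
correlationDissimilarity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("at least 3 voxels are required")
  v <- apply(ts, 1L, stats::var)
  if (any(v <= 0))
    stop("zero-variance voxel(s): ", paste(which(v <= 0), collapse = ", "))
  C <- stats::cor(t(ts))
  D <- as.matrix(stats::dist(C, method = "euclidean"))
  dimnames(D) <- list(rownames(ts), rownames(ts))
  D
}

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Hierarchical agglomerative clustering of the precomputed dissimilarity,
#' cut at `k` clusters. Deterministic given `D` and the linkage.
#'
#' @param D symmetric dissimilarity matrix (e.g.
#'   [correlationDissimilarity()]).
#' @param k number of clusters (default 3: two stimulated compartments plus
#'   unstimulated tissue).
#' @param linkage one of `"average"`, `"complete"`, `"ward"` (ward.D2).
#' @return A [ClusterResult-class].
#' @export
clusterVoxels <- function(D, k = 3L, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  n <- nrow(D)
  if (k > n) stop("k cannot exceed the number of voxels")
  hc <- stats::hclust(stats::as.dist(D),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  labels <- as.integer(stats::cutree(hc, k = k))
  new("ClusterResult", labels = labels, D = D, linkage = linkage,
      k = as.integer(k), hclust = hc)
}

#' Concatenate two experiments in time
#'
#' Converts each experiment to percent signal change voxelwise, then joins
#' them column-wise. Row (voxel) counts must match.
#'
#' @param tsA,tsB voxel-by-time matrices over the same voxels.
#' @return voxel-by-time matrix with `ncol(tsA) + ncol(tsB)` columns.
#' @export
concatExperiments <- function(tsA, tsB) {
  tsA <- as.matrix(tsA)
  tsB <- as.matrix(tsB)
  if (nrow(tsA) != nrow(tsB))
    stop("experiments must cover the same voxels (row counts differ)")
  cbind(percentSignalChange(tsA), percentSignalChange(tsB))
}

#' Regress pRF estimates on cluster labels
#'
#' Fits a multinomial logistic regression of the cluster labels on the six
#' z-scored pRF parameter estimates (polar angle, eccentricity, sigma, omega,
#' beta, mu), and a companion linear model of the numeric labels on the same
#' standardized predictors providing an overall F statistic, its p-value and
#' r-squared together with standardized coefficients. Both fits are reported
#' because an F statistic is a linear-model quantity while the labels are
#' categorical; the multinomial fit treats them as such.
#'
#' @param params data.frame (>= 20 rows) of per-voxel estimates with columns
#'   `polar`, `ecc`, `sigma`, `omega`, `beta`, `mu` (or `x0`/`y0`, which are
#'   converted to polar coordinates).
#' @param labels cluster labels, one per voxel.
#' @return list with elements
#'   \describe{
#'     \item{linear}{data.frame of standardized coefficient, SE, p per
#'       parameter from the companion linear model.}
#'     \item{fStatistic, fP, r2}{overall linear-model summary.}
#'     \item{multinomial}{data.frame of coefficient, SE, p per parameter and
#'       label contrast from the multinomial logistic fit.}
#'     \item{separationWarning}{TRUE when quasi-separation was detected.}
#'   }
#' @export
regressLabels <- function(params, labels) {
  params <- as.data.frame(params)
  if (!"polar" %in% names(params) && all(c("x0", "y0") %in% names(params))) {
    pol <- cartesianToPolar(params$x0, params$y0)
    params$polar <- pol$polar_deg
    params$ecc <- pol$ecc_deg
  }
  need <- c("polar", "ecc", "sigma", "omega", "beta", "mu")
  if (!all(need %in% names(params)))
    stop("params must provide columns ", paste(need, collapse = ", "))
  if (nrow(params) < 20L) stop("at least 20 voxels are required")
  if (nrow(params) != length(labels)) stop("one label per voxel is required")
  X <- scale(as.matrix(params[need]))
  X[, attr(X, "scaled:scale") == 0] <- 0
  df <- data.frame(label = factor(labels), X)

  # companion linear model: standardized response on standardized predictors
  z <- as.numeric(scale(as.numeric(labels)))
  lmFit <- stats::lm(z ~ ., data = data.frame(z = z, X))
  sm <- summary(lmFit)
  co <- stats::coef(sm)
  # constant or aliased predictors are reported with NA coefficients
  idx <- match(need, rownames(co))
  linear <- data.frame(parameter = need,
                       beta = co[idx, 1], se = co[idx, 2], p = co[idx, 4],
                       row.names = NULL)
  fstat <- sm$fstatistic
  fP <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)

  mn <- nnet::multinom(label ~ ., data = df, trace = FALSE, maxit = 200L)
  cf <- stats::coef(mn)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L, dimnames = list("2", names(cf)))
  se <- tryCatch(summary(mn)$standard.errors, error = function(e) cf * NA)
  if (is.null(dim(se))) se <- matrix(se, nrow = 1L, dimnames = dimnames(cf))
  zstat <- cf / se
  pv <- 2 * stats::pnorm(-abs(zstat))
  keep <- colnames(cf) %in% need
  multi <- do.call(rbind, lapply(rownames(cf), function(lv) {
    data.frame(contrast = lv, parameter = colnames(cf)[keep],
               coef = cf[lv, keep], se = se[lv, keep], p = pv[lv, keep],
               row.names = NULL)
  }))
  sep <- any(abs(cf[, keep]) > 15, na.rm = TRUE)
  if (sep)
    warning("possible quasi-separation in the multinomial fit; ",
            "coefficients reported but unstable")
  list(linear = linear,
       fStatistic = unname(fstat[1]), fDf = unname(fstat[2:3]),
       fP = unname(fP), r2 = sm$r.squared,
       multinomial = multi, separationWarning = sep)
}
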