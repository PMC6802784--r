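test_that("correlation dissimilarity matches a first-principles 3-voxel computation", {
  ts <- rbind(c(1, 2, 3, 5, 4), c(2, 1, 4, 3, 6), c(5, 3, 2, 1, 0))
  # oracle: Pearson correlations from the definition, then row distances
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  C <- diag(3)
  for (i in 1:2) for (j in (i + 1):3)
    C[i, j] <- C[j, i] <- pearson(ts[i, ], ts[j, ])
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    want[i, j] <- sqrt(sum((C[i, ] - C[j, ])^2))
  D <- correlationDissimilarity(ts)
  expect_equal(unname(D), want, tolerance = 1e-12)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)

  # identical voxels are at distance zero; a voxel and its negation are not
  ts2 <- rbind(ts, ts[1, ])
  D2 <- correlationDissimilarity(ts2)
  expect_equal(D2[1, 4], 0)
  # permutation consistency
  perm <- c(3, 1, 2)
  expect_equal(unname(correlationDissimilarity(ts[perm, ])),
               unname(D[perm, perm]))
  expect_error(correlationDissimilarity(rbind(ts, rep(1, 5))),
               "zero-variance")
  expect_error(correlationDissimilarity(ts[1:2, ]), "3 voxels")
})

test_that("agglomerative clustering recovers planted families and handles edge cases", {
  cp <- makeClusterPhantom(nPerGroup = 25L, driver = "beta", seed = 2L)
  D <- correlationDissimilarity(percentSignalChange(cp$ts))
  cl <- clusterVoxels(D, k = 3L)
  expect_ari(clusterLabels(cl), cp$labels, min = 1)

  cpo <- makeClusterPhantom(nPerGroup = 25L, driver = "omega",
                            noiseScale = 0.15, seed = 2L)
  clo <- clusterVoxels(correlationDissimilarity(percentSignalChange(cpo$ts)),
                       k = 3L)
  expect_ari(clusterLabels(clo), cpo$labels, min = 1)

  # k = n gives singletons
  small <- D[1:5, 1:5]
  expect_equal(sort(clusterLabels(clusterVoxels(small, k = 5L))), 1:5)
  expect_error(clusterVoxels(small, k = 6L), "exceed")

  # duplicating every voxel leaves memberships invariant (balanced subset,
  # 10 voxels per family)
  ts <- percentSignalChange(cp$ts)[c(1:10, 26:35, 51:60), ]
  lab1 <- clusterLabels(clusterVoxels(correlationDissimilarity(ts), k = 3L))
  lab2 <- clusterLabels(clusterVoxels(
    correlationDissimilarity(rbind(ts, ts)), k = 3L))
  expect_ari(lab2[1:30], lab1, min = 1)
  expect_equal(lab2[1:30], lab2[31:60])

  # invariance to common affine rescaling of the series
  lab3 <- clusterLabels(clusterVoxels(
    correlationDissimilarity(ts * 3.7 + 2), k = 3L))
  expect_ari(lab3, lab1, min = 1)
})

test_that("experiments concatenate in time after percent-signal-change", {
  a <- matrix(stats::runif(40, 10, 20), nrow = 4)
  b <- matrix(stats::runif(60, 10, 20), nrow = 4)
  cc <- concatExperiments(a, b)
  expect_equal(dim(cc), c(4L, ncol(a) + ncol(b)))
  expect_error(concatExperiments(a, b[1:3, ]), "row counts")
  # self-concatenation doubles columns, correlation matrix unchanged
  selfc <- concatExperiments(a, a)
  expect_equal(stats::cor(t(selfc)), stats::cor(t(percentSignalChange(a))),
               tolerance = 1e-12)
})

test_that("label regression singles out the planted driver parameter", {
  cp <- makeClusterPhantom(nPerGroup = 25L, driver = "beta", seed = 2L)
  cl <- clusterVoxels(correlationDissimilarity(percentSignalChange(cp$ts)),
                      k = 3L)
  reg <- suppressWarnings(regressLabels(cp$params, clusterLabels(cl)))
  lin <- reg$linear
  expect_equal(lin$parameter[which.max(abs(lin$beta))], "beta")
  expect_lt(lin$p[lin$parameter == "beta"], 0.01)
  expect_gt(lin$p[lin$parameter == "omega"], 0.05)   # non-driver n.s.
  expect_true(is.na(lin$beta[lin$parameter == "mu"])) # constant -> NA
  expect_lt(reg$fP, 0.001)
  # one row per (label contrast, fitted parameter)
  expect_equal(nrow(reg$multinomial) %% 2L, 0L)
  expect_setequal(unique(reg$multinomial$contrast), c("2", "3"))

  # balanced duplication leaves the linear coefficients identical
  reg2 <- suppressWarnings(regressLabels(rbind(cp$params, cp$params),
                                         rep(clusterLabels(cl), 2)))
  expect_equal(reg2$linear$beta, lin$beta, tolerance = 1e-9)

  # random labels: the overall test is n.s. at alpha = 0.05 in >= 90% of seeds
  ns <- vapply(1:40, function(s) {
    lab <- withSeed(500 + s, sample(1:3, nrow(cp$params), replace = TRUE))
    suppressWarnings(regressLabels(cp$params, lab))$fP > 0.05
  }, logical(1))
  expect_gte(mean(ns), 0.9)

  expect_error(regressLabels(cp$params[1:10, ], clusterLabels(cl)[1:10]),
               "20 voxels")
})
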