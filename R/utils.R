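#' @importFrom withr with_seed
NULL

# Evaluate expr with a private RNG seeded at `seed`, restoring global state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Causal FFT convolution of each column of x (n x m) with kernel h,
# zero-padded start, truncated to nrow(x).
.causalConv <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  nh <- length(h)
  nfft <- stats::nextn(n + nh - 1L, 2L)
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y[seq_len(n), , drop = FALSE]
}

# Zero-phase convolution of vector x with a kernel whose center is at
# index i0 (1-based); zero-padded edges, output length length(x).
.centeredConv <- function(x, k, i0) {
  n <- length(x)
  nk <- length(k)
  nfft <- stats::nextn(n + nk - 1L, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(k, rep(0, nfft - nk)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  y[seq(i0, i0 + n - 1L)]
}

# Ordinary least squares of obs on a single predictor plus intercept.
# Returns c(beta, mu, rss). Degenerate (constant) predictors get beta = 0.
.olsBetaMu <- function(pred, obs) {
  pm <- mean(pred)
  om <- mean(obs)
  vp <- sum((pred - pm)^2)
  if (vp < 1e-300) {
    beta <- 0
    mu <- om
  } else {
    beta <- sum((pred - pm) * (obs - om)) / vp
    mu <- om - beta * pm
  }
  resid <- obs - mu - beta * pred
  c(beta = beta, mu = mu, rss = sum(resid^2))
}

# OLS of obs on [1, bS, bT] where bS/bT are the per-channel hemodynamic
# predictions; the channel amplitudes a = omega*beta and c = (1-omega)*beta
# must share a sign for omega to lie in [0, 1], so sign-inconsistent
# solutions fall back to the better single-channel (boundary omega) fit.
.olsChannels <- function(bS, bT, obs) {
  X <- cbind(1, bS, bT)
  fit <- stats::.lm.fit(X, obs)
  cf <- fit$coefficients
  a <- cf[2]; c_ <- cf[3]
  if (!all(is.finite(cf)) || (a * c_ < 0)) {
    f1 <- .olsBetaMu(bS, obs)   # omega = 1
    f0 <- .olsBetaMu(bT, obs)   # omega = 0
    if (f1[["rss"]] <= f0[["rss"]])
      return(list(rss = f1[["rss"]], omega = 1, beta = f1[["beta"]],
                  mu = f1[["mu"]]))
    return(list(rss = f0[["rss"]], omega = 0, beta = f0[["beta"]],
                mu = f0[["mu"]]))
  }
  beta <- a + c_
  omega <- if (abs(beta) < 1e-300) 0.5 else a / beta
  list(rss = sum(fit$residuals^2), omega = min(max(omega, 0), 1),
       beta = beta, mu = cf[1])
}

# r2 of a prediction against observations.
.r2 <- function(rss, obs) {
  tss <- sum((obs - mean(obs))^2)
  if (tss <= 0) return(NA_real_)
  1 - rss / tss
}

#' Convert Cartesian pRF centers to polar coordinates
#'
#' @param x0,y0 pRF centers (deg).
#' @return data.frame with `polar_deg` in `[0, 360)` and `ecc_deg`.
#' @export
cartesianToPolar <- function(x0, y0) {
  data.frame(
    polar_deg = (atan2(y0, x0) * 180 / pi) %% 360,
    ecc_deg = sqrt(x0^2 + y0^2)
  )
}
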