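#' EEG frequency band definitions
#'
#' The four analysis bands: delta 1-4 Hz, theta 5-7 Hz, alpha 8-12 Hz,
#' beta 13-20 Hz (inclusive integer-Hz edges; the bands are disjoint,
#' so with 1-s epochs the 4 Hz bin belongs to delta only and the 5 Hz
#' bin to theta only).
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(1, 5, 8, 13), hi = c(4, 7, 12, 20))
}

# lagged design matrix: columns are x_{t-1}, ..., x_{t-p} for t in
# (p+1):n restricted to `t_keep`
.lag_design <- function(x, p, t_keep) {
  out <- matrix(0, length(t_keep), p)
  for (j in seq_len(p)) out[, j] <- x[t_keep - j]
  out
}

#' Select the bivariate VAR order by BIC
#'
#' Fits the bivariate vector autoregression of `(x, y)` for each order
#' `1..p_max` on the common effective sample and returns the order
#' minimizing the Bayesian Information Criterion
#' `N log det(Sigma) + n_par log N`.
#'
#' @param x,y Numeric series of equal length (> `10 * p_max`).
#' @param p_max Largest candidate order.
#' @return Integer order in `1..p_max`.
#' @export
fit_var_order_bic <- function(x, y, p_max = 8L) {
  p_max <- as.integer(p_max)
  stopifnot(p_max >= 1L, length(x) == length(y))
  n <- length(x)
  if (n <= 10L * p_max) stop("series too short for p_max = ", p_max)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  t_keep <- (p_max + 1L):n  # common sample across orders
  N <- length(t_keep)
  bic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    X <- cbind(1, .lag_design(x, p, t_keep), .lag_design(y, p, t_keep))
    rx <- stats::.lm.fit(X, x[t_keep])$residuals
    ry <- stats::.lm.fit(X, y[t_keep])$residuals
    Sigma <- crossprod(cbind(rx, ry)) / N
    det_s <- det(Sigma)
    if (!is.finite(det_s) || det_s <= 0) stop("singular residual covariance")
    n_par <- 2 * (2 * p + 1)
    bic[p] <- N * log(det_s) + n_par * log(N)
  }
  which.min(bic)
}

#' Bivariate Granger causality
#'
#' Measures the linear predictive improvement of adding `p` lags of
#' the source `y` to the sink's autoregression:
#' `gc = log(sigma2_restricted / sigma2_full)` in nats, where the
#' residual variances come from least-squares fits of `x_t` on its own
#' lags (restricted) and on its own plus the source's lags (full).
#' Non-negative up to numerical tolerance, and invariant to separate
#' rescaling of the two series.
#'
#' @param x Sink series.
#' @param y Source series.
#' @param p VAR order (see [fit_var_order_bic()]).
#' @param details If `TRUE` also return a test of the source lags'
#'   joint significance.
#' @param robust With `details = TRUE`: use a HAC-robust
#'   (Newey-West) Wald test instead of the classical F-test. The
#'   classical test assumes homoskedastic, serially uncorrelated
#'   errors and over-rejects when the true coupling is nonlinear (the
#'   omitted term leaves heteroskedastic, dependent residuals); the
#'   robust test stays correctly sized in that regime.
#' @param hac_lags Newey-West truncation lag for the robust test;
#'   default the usual `4 (n/100)^{2/9}` rule.
#' @return The GC value in nats, or (with `details = TRUE`) a list
#'   with `gc`, the test statistic (`F` or `W`), `p_value`, degrees of
#'   freedom and `n`.
#' @export
granger <- function(x, y, p, details = FALSE, robust = FALSE,
                    hac_lags = NULL) {
  p <- as.integer(p)
  stopifnot(p >= 1L, length(x) == length(y))
  n <- length(x)
  if (n <= 3L * p + 2L) stop("series too short for order ", p)
  if (stats::sd(x) == 0) stop("constant sink series")
  t_keep <- (p + 1L):n
  N <- length(t_keep)
  Xr <- cbind(1, .lag_design(x, p, t_keep))
  Xf <- cbind(Xr, .lag_design(y, p, t_keep))
  rss_r <- sum(stats::.lm.fit(Xr, x[t_keep])$residuals^2)
  fit_f <- stats::.lm.fit(Xf, x[t_keep])
  rss_f <- sum(fit_f$residuals^2)
  if (!is.finite(rss_f) || rss_f <= 0) stop("non-finite or zero residual variance")
  gc <- log(rss_r / rss_f)
  if (!details) return(gc)
  if (!robust) {
    df2 <- N - 2L * p - 1L
    Fstat <- ((rss_r - rss_f) / p) / (rss_f / df2)
    return(list(gc = gc, F = Fstat,
                p_value = stats::pf(Fstat, p, df2, lower.tail = FALSE),
                df1 = p, df2 = df2, n = N))
  }
  if (is.null(hac_lags)) hac_lags <- max(1L, floor(4 * (N / 100)^(2 / 9)))
  S <- Xf * fit_f$residuals            # score contributions
  G <- crossprod(S) / N
  for (l in seq_len(hac_lags)) {
    w <- 1 - l / (hac_lags + 1)        # Bartlett kernel
    Gl <- crossprod(S[1:(N - l), , drop = FALSE],
                    S[(1 + l):N, , drop = FALSE]) / N
    G <- G + w * (Gl + t(Gl))
  }
  B <- solve(crossprod(Xf) / N)
  V <- B %*% G %*% B / N
  idx <- (p + 2L):(2L * p + 1L)        # the source-lag coefficients
  b <- fit_f$coefficients[idx]
  W <- as.numeric(t(b) %*% solve(V[idx, idx]) %*% b)
  list(gc = gc, W = W,
       p_value = stats::pchisq(W, df = p, lower.tail = FALSE),
       df = p, hac_lags = hac_lags, n = N)
}

#' Band power of an epoch by FFT
#'
#' One-sided periodogram power (rectangular taper) summed over the
#' bins whose frequency lies in `[lo, hi]` inclusive. With the 1-s
#' epochs used throughout, bins fall on integer frequencies and the
#' bands of [eeg_bands()] are disjoint. A unit-amplitude in-band
#' sinusoid at an exact bin yields power 0.5 (its variance).
#'
#' @param epoch Numeric series (one baseline epoch).
#' @param fs Sampling rate in Hz.
#' @param band One row of [eeg_bands()] or any list with `lo`, `hi`.
#' @return Band power in squared signal units.
#' @export
band_power <- function(epoch, fs, band) {
  n <- length(epoch)
  if (band$hi > fs / 2) stop("band extends above the Nyquist frequency")
  X <- stats::fft(epoch)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sel <- half & freqs >= band$lo & freqs <= band$hi
  sum(2 * Mod(X[sel])^2 / n^2)
}

#' Per-trial band powers for every channel and band
#'
#' @param epochs An `eeg_epochs` array.
#' @param bands Band table, default [eeg_bands()].
#' @return Long data frame: `trial` (epoch position), `channel`,
#'   `band`, `power`.
#' @export
band_power_table <- function(epochs, bands = eeg_bands()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- attr(epochs, "fs")
  chans <- attr(epochs, "channels")
  nt <- dim(epochs)[2]
  out <- vector("list", length(chans) * nrow(bands))
  k <- 0L
  for (ci in seq_along(chans)) {
    em <- channel_epochs(epochs, ci)
    for (bi in seq_len(nrow(bands))) {
      b <- bands[bi, ]
      pw <- apply(em, 1, band_power, fs = fs, band = b)
      k <- k + 1L
      out[[k]] <- data.frame(trial = seq_len(nt), channel = chans[ci],
                             band = bands$name[bi], power = pw)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation between band power and DP
#'
#' @param band_powers Per-trial band-power values.
#' @param dps Per-trial DP values (same length, >= 3 trials).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
band_dp_correlation <- function(band_powers, dps) {
  if (length(band_powers) != length(dps)) stop("length mismatch")
  if (length(dps) < 3L) stop("need at least 3 trials")
  if (!all(is.finite(band_powers)) || !all(is.finite(dps))) {
    stop("non-finite values")
  }
  if (stats::sd(band_powers) == 0 || stats::sd(dps) == 0) {
    stop("zero variance in band powers or DPs")
  }
  stats::cor(band_powers, dps)
}
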