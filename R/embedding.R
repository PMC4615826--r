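#' Embedding specification for transfer-entropy estimation
#'
#' Bundles the delay-embedding and estimator parameters: sink embedding
#' dimension `d`, source embedding dimension `m`, embedding delay `tau`
#' (samples), prediction time `u` (samples), neighbor count `k` and
#' Theiler exclusion window `theiler` (samples).
#'
#' @param d,m Embedding dimensions (>= 1) of sink and source states.
#' @param tau Embedding delay in samples (>= 1).
#' @param u Prediction time in samples (>= 1): the lead between the
#'   embedded past states and the sink sample being predicted.
#' @param k Neighbor count of the Kraskov estimator (default 4).
#' @param theiler Theiler window in samples (default 1): temporal
#'   neighbors within this window are excluded from neighbor searches
#'   to suppress autocorrelation bias.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(d = 1L, m = 1L, tau = 1L, u = 1L, k = 4L,
                           theiler = 1L) {
  d <- as.integer(d); m <- as.integer(m); tau <- as.integer(tau)
  u <- as.integer(u); k <- as.integer(k); theiler <- as.integer(theiler)
  stopifnot(d >= 1L, m >= 1L, tau >= 1L, u >= 1L, k >= 1L, theiler >= 0L)
  structure(list(d = d, m = m, tau = tau, u = u, k = k, theiler = theiler),
            class = "embedding_spec")
}

#' @export
print.embedding_spec <- function(x, ...) {
  cat(sprintf("embedding_spec: d=%d m=%d tau=%d u=%d k=%d theiler=%d\n",
              x$d, x$m, x$tau, x$u, x$k, x$theiler))
  invisible(x)
}

#' Delay embedding of a scalar series
#'
#' Builds the sequence of delay-coordinate state vectors
#' `(x_t, x_{t-tau}, ..., x_{t-(dim-1) tau})` for all admissible `t`.
#'
#' @param x Numeric series.
#' @param dim Embedding dimension (>= 1).
#' @param tau Embedding delay in samples (>= 1).
#' @return A matrix with `length(x) - (dim - 1) * tau` rows; row `i`
#'   is the state at time `t = (dim - 1) * tau + i`, columns ordered
#'   from the current sample backwards.
#' @examples
#' delay_embed(1:5, dim = 2, tau = 1)
#' @export
delay_embed <- function(x, dim, tau) {
  dim <- as.integer(dim); tau <- as.integer(tau)
  stopifnot(dim >= 1L, tau >= 1L)
  n <- length(x)
  horizon <- (dim - 1L) * tau
  if (n < horizon + 1L) stop("series too short for this embedding")
  nv <- n - horizon
  out <- matrix(0, nv, dim)
  for (j in seq_len(dim)) {
    out[, j] <- x[(horizon + 1L - (j - 1L) * tau):(n - (j - 1L) * tau)]
  }
  out
}

#' Select the embedding delay from the autocorrelation decay
#'
#' Returns the first lag at which the sample autocorrelation of `x`
#' falls below `1/e`. This is the package's delay-selection policy for
#' state-space reconstruction; the companion dimension search is
#' [cao_dimension()].
#'
#' @param x Numeric series (length >= 500 recommended).
#' @param max_lag Largest lag examined; default `min(n - 1, 100)`.
#' @return The selected delay, an integer >= 1.
#' @export
select_delay <- function(x, max_lag = NULL) {
  n <- length(x)
  if (n < 20L) stop("series too short for delay selection")
  if (stats::sd(x) == 0) stop("constant series: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- min(n - 1L, 100L)
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  hit <- which(r < exp(-1))
  if (length(hit) == 0L) return(as.integer(max_lag))
  as.integer(hit[1])
}

#' Cao's embedding statistics E1 and E2
#'
#' Computes Cao's `E1(d) = E(d + 1) / E(d)` and `E2(d)` over
#' `d = 1, ..., d_max`, where `E(d)` averages the ratio of
#' nearest-neighbor distances in dimensions `d + 1` and `d`
#' (Chebyshev norm) and `E2` is based on the one-step-ahead
#' divergence of the same neighbors. `E1` saturating near 1 signals a
#' sufficient embedding dimension; `E2` staying near 1 for all `d` is
#' the signature of a stochastic series.
#'
#' @param x Numeric series (length >= a few hundred).
#' @param tau Embedding delay (see [select_delay()]).
#' @param d_max Largest candidate dimension (>= 2).
#' @param theiler Theiler window for the neighbor search (default 0:
#'   only the point itself is excluded).
#' @return A data frame with columns `d`, `E1`, `E2`.
#' @references Cao, L. (1997) Practical method for determining the
#'   minimum embedding dimension of a scalar time series. Physica D.
#' @export
cao_statistics <- function(x, tau, d_max, theiler = 0L) {
  tau <- as.integer(tau); d_max <- as.integer(d_max)
  stopifnot(tau >= 1L, d_max >= 2L)
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant series")
  if (n < (d_max + 1L) * tau + 20L) stop("series too short for d_max embedding")
  x <- .tiny_jitter(x)
  E <- Estar <- rep(NA_real_, d_max + 1L)
  for (d in seq_len(d_max + 1L)) {
    # forward-indexed embedding y_d(i) = (x_i, x_{i+tau}, ...); align all
    # dimensions on the index range valid for dimension d + 1
    n_pts <- n - d * tau
    if (n_pts < 2L) break
    yd <- matrix(0, n_pts, d)
    for (j in seq_len(d)) yd[, j] <- x[(1L + (j - 1L) * tau):(n_pts + (j - 1L) * tau)]
    nxt <- x[(1L + d * tau):(n_pts + d * tau)]  # coordinate added at dim d + 1
    nn <- nn1_cpp(yd, rep(1L, n_pts), seq_len(n_pts), as.integer(theiler))
    ok <- !is.na(nn$index)
    i <- which(ok); j <- nn$index[ok]
    dd <- nn$dist[ok]
    d_plus <- pmax(dd, abs(nxt[i] - nxt[j]))
    E[d] <- mean(d_plus / dd)
    Estar[d] <- mean(abs(nxt[i] - nxt[j]))
  }
  d_seq <- seq_len(d_max)
  data.frame(d = d_seq, E1 = E[d_seq + 1L] / E[d_seq],
             E2 = Estar[d_seq + 1L] / Estar[d_seq])
}

#' Select the embedding dimension by Cao's criterion
#'
#' Returns the smallest dimension at which Cao's `E1` statistic has
#' saturated (`|E1(d) - 1| < tol`), capped at `d_max`.
#'
#' @inheritParams cao_statistics
#' @param tol Saturation tolerance on `|E1 - 1|` (default 0.05).
#' @return An integer dimension in `1..d_max`.
#' @export
cao_dimension <- function(x, tau, d_max = 8L, tol = 0.05, theiler = 0L) {
  st <- cao_statistics(x, tau, d_max, theiler)
  hit <- which(abs(st$E1 - 1) < tol)
  if (length(hit) == 0L) return(as.integer(d_max))
  as.integer(min(hit[1] + 1L, d_max))
}

# Deterministic tie-breaking jitter for the rank-based neighbor
# machinery: amplitude 1e-10 of the series scale, generated by a fixed
# linear congruential sequence so results are reproducible without
# touching the R RNG.
.tiny_jitter <- function(x, amp = 1e-10) {
  n <- length(x)
  s <- (1664525 * (seq_len(n) %% 65536) + 1013904223) %% 4294967296
  scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) scale <- 1
  x + amp * scale * (s / 4294967296 - 0.5)
}
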