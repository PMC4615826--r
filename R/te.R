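#' Transfer entropy by the Kraskov k-nearest-neighbor estimator
#'
#' Estimates the directed transfer entropy from `source` to `sink` as
#' the conditional mutual information
#' \eqn{I(x_{t+u};\, \mathbf{y}^m_t \mid \mathbf{x}^d_t)} between the
#' sink's future sample, the source's embedded past and the sink's
#' embedded past, using Kraskov-style neighbor counting (algorithm 1,
#' Chebyshev norm, single combined neighbor search) with Theiler
#' exclusion of temporal neighbors. The population quantity is >= 0;
#' the estimator is approximately unbiased and may return small
#' negative values on finite data.
#'
#' @param source,sink Numeric vectors (one trial) or matrices with one
#'   trial per row (pooled estimation: state vectors from all trials
#'   are combined, and neighbor searches never cross trial boundaries
#'   closer than the Theiler window within a trial).
#' @param spec An [embedding_spec()].
#' @return An object of class `te_result`: list with `te_bits`,
#'   `te_nats`, `direction` (c(source, sink) labels), `spec`,
#'   `n_effective` (state vectors used) and `n_trials`.
#' @details Values are reported in bits (natural-log internally). A
#'   deterministic sub-numerical-precision jitter breaks distance ties
#'   so the rank-based estimator is well defined on data with repeated
#'   values; it leaves continuous-valued estimates unchanged to ~1e-9.
#' @seealso [surrogate_test()], [select_u()], [embedding_spec()]
#' @export
ksg_te <- function(source, sink, spec = embedding_spec()) {
  emb <- .te_embed(source, sink, spec)
  res <- ksg_cmi_cpp(emb$xf, emb$xp, emb$yp, emb$trial, emb$tm,
                     spec$k, spec$theiler)
  structure(list(te_bits = res$cmi_nats / log(2),
                 te_nats = res$cmi_nats,
                 direction = c(source = .series_label(source, "Y"),
                               sink = .series_label(sink, "X")),
                 spec = spec,
                 n_effective = res$n,
                 n_trials = emb$n_trials),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("TE(%s -> %s) = %.4f bits  (n_eff = %d, d=%d m=%d tau=%d u=%d k=%d T=%d)\n",
              x$direction["source"], x$direction["sink"], x$te_bits,
              x$n_effective, x$spec$d, x$spec$m, x$spec$tau, x$spec$u,
              x$spec$k, x$spec$theiler))
  invisible(x)
}

.series_label <- function(x, fallback) {
  lb <- attr(x, "label")
  if (is.null(lb)) fallback else lb
}

# Build the embedded future/past matrices for one or several trials.
# Points of one trial are contiguous and in time order, which the
# Theiler bookkeeping in the C++ layer relies on.
.te_embed <- function(source, sink, spec) {
  if (is.matrix(source) || is.matrix(sink)) {
    if (!is.matrix(source) || !is.matrix(sink) ||
        !all(dim(source) == dim(sink))) {
      stop("'source' and 'sink' must have identical trial layout")
    }
    trials_src <- lapply(seq_len(nrow(source)), function(i) source[i, ])
    trials_snk <- lapply(seq_len(nrow(sink)), function(i) sink[i, ])
  } else {
    if (length(source) != length(sink)) stop("series lengths differ")
    trials_src <- list(as.numeric(source))
    trials_snk <- list(as.numeric(sink))
  }
  d <- spec$d; m <- spec$m; tau <- spec$tau; u <- spec$u
  horizon <- (max(d, m) - 1L) * tau
  xf <- numeric(0); tm <- integer(0); trial <- integer(0)
  xp_l <- list(); yp_l <- list()
  for (i in seq_along(trials_src)) {
    y <- trials_src[[i]]; x <- trials_snk[[i]]
    if (anyNA(x) || anyNA(y)) stop("NaN/NA samples in input")
    n <- length(x)
    n_eff <- n - u - horizon
    if (n_eff < spec$k + 2L) {
      stop("series too short for this embedding (n_eff = ", n_eff, ")")
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance series")
    # per-trial z-scoring: makes the estimate exactly invariant to
    # separate affine rescaling of source and sink and puts pooled
    # trials on a common amplitude scale
    x <- (x - mean(x)) / stats::sd(x)
    y <- (y - mean(y)) / stats::sd(y)
    x <- .tiny_jitter(x); y <- .tiny_jitter(y, amp = 1.7e-10)
    xe <- delay_embed(x, d, tau)   # rows: t = (d-1)tau .. n-1 (0-based end)
    ye <- delay_embed(y, m, tau)
    # align both embeddings and the future on t = horizon+1 .. n-u (1-based)
    t_idx <- seq(horizon + 1L, n - u)
    xp <- xe[t_idx - (d - 1L) * tau, , drop = FALSE]
    yp <- ye[t_idx - (m - 1L) * tau, , drop = FALSE]
    xf <- c(xf, x[t_idx + u])
    xp_l[[i]] <- xp; yp_l[[i]] <- yp
    tm <- c(tm, seq_along(t_idx))
    trial <- c(trial, rep(i, length(t_idx)))
  }
  list(xf = xf, xp = do.call(rbind, xp_l), yp = do.call(rbind, yp_l),
       tm = as.integer(tm), trial = as.integer(trial),
       n_trials = length(trials_src))
}

#' Select the prediction time maximizing transfer entropy
#'
#' Evaluates [ksg_te()] for each candidate prediction time (given in
#' milliseconds and converted to samples by round-half-up with a floor
#' of one sample) and returns the candidate with the largest estimate;
#' ties resolve to the smallest prediction time.
#'
#' @inheritParams ksg_te
#' @param candidates_ms Candidate prediction times in milliseconds
#'   (default the scanning set 5, 10, 20, 40, 60, 80, 100 ms).
#' @param fs Sampling rate in Hz.
#' @return A list with `u` (samples), `u_ms` (the winning candidate),
#'   `te_bits` (estimates for every candidate, named by ms).
#' @export
select_u <- function(source, sink, spec = embedding_spec(),
                     candidates_ms = c(5, 10, 20, 40, 60, 80, 100),
                     fs = 250) {
  if (length(candidates_ms) == 0L) stop("empty candidate list")
  u_samp <- ms_to_samples(candidates_ms, fs)
  te <- rep(NA_real_, length(u_samp))
  for (i in seq_along(u_samp)) {
    sp <- spec; sp$u <- u_samp[i]
    te[i] <- tryCatch(ksg_te(source, sink, sp)$te_bits, error = function(e) NA_real_)
  }
  if (all(is.na(te))) stop("all candidate prediction times exceed the usable series length")
  names(te) <- as.character(candidates_ms)
  # max TE; ties (and equal u from ms rounding) resolve to smallest u
  ord <- order(-te, u_samp, na.last = TRUE)
  best <- ord[1]
  list(u = u_samp[best], u_ms = candidates_ms[best], te_bits = te)
}

#' Convert milliseconds to samples
#'
#' Round-half-up conversion with a floor of one sample, e.g. 5 ms at
#' 250 Hz is 1 sample and 10 ms is 3 samples.
#'
#' @param ms Durations in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Integer sample counts, >= 1.
#' @export
ms_to_samples <- function(ms, fs) {
  pmax(1L, as.integer(floor(ms * fs / 1000 + 0.5)))
}

#' Surrogate significance test for transfer entropy
#'
#' Builds a null distribution of the TE estimate by destroying the
#' source-sink temporal relationship: with multi-trial input the
#' source trials are shuffled across trials; with a single trial the
#' source is circularly shifted by a random offset. The p-value is the
#' permutation tail probability `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams ksg_te
#' @param n_perm Number of surrogates (>= 100 recommended; must be >= 1).
#' @param seed Integer seed for the surrogate randomization.
#' @param min_shift Minimum circular shift (single-trial null), in
#'   samples; default 25.
#' @param alpha_stop Optional sequential-stopping level (Besag &
#'   Clifford): the permutation loop halts as soon as enough null
#'   values exceed the observed one that rejection at this level has
#'   become impossible. The accept/reject decision at `alpha_stop` is
#'   identical to running all `n_perm` surrogates; the reported
#'   p-value is then the (conservative) sequential estimate `h / m`.
#' @return List with `p_value`, `te_obs` (bits), `null_te` (bits, the
#'   surrogates actually computed) and `n_perm`.
#' @export
surrogate_test <- function(source, sink, spec = embedding_spec(),
                           n_perm = 200L, seed = 1L, min_shift = 25L,
                           alpha_stop = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  h_stop <- if (!is.null(alpha_stop)) ceiling(alpha_stop * (n_perm + 1L))
  obs <- ksg_te(source, sink, spec)$te_bits
  null_te <- numeric(0)
  multi <- is.matrix(source) && nrow(source) > 1L
  if (!multi && is.matrix(source)) source <- source[1, ]
  if (!multi && is.matrix(sink)) sink <- sink[1, ]
  if (!multi) {
    n <- length(source)
    if (n < 2L * min_shift + 2L) stop("series too short for the circular-shift null")
  }
  cnt <- 0L
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (multi) {
        perm <- sample(nrow(source))
        # avoid the identity permutation (it reproduces the observed value)
        while (all(perm == seq_len(nrow(source)))) perm <- sample(nrow(source))
        src_b <- source[perm, , drop = FALSE]
      } else {
        off <- sample(seq(min_shift, length(source) - min_shift), 1L)
        src_b <- c(source[(off + 1L):length(source)], source[seq_len(off)])
      }
      te_b <- ksg_te(src_b, sink, spec)$te_bits
      null_te[b] <- te_b
      if (te_b >= obs) cnt <- cnt + 1L
      if (!is.null(h_stop) && cnt >= h_stop) break
    }
  })
  m <- length(null_te)
  p <- if (m < n_perm) cnt / m else (1 + cnt) / (1 + n_perm)
  list(p_value = p, te_obs = obs, null_te = null_te, n_perm = n_perm)
}

# evaluate `code` under a temporary RNG state seeded by `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic stage seed derived from a run seed and a label.
# FNV-1a over the label bytes and the seed bytes: nearby labels or
# seeds map to well-separated outputs. Mersenne-Twister streams seeded
# from near-identical integers start correlated, so the avalanche here
# is essential for treating derived streams as independent.
derive_seed <- function(seed, label) {
  xor32 <- function(a, b) {
    al <- a %% 65536; ah <- (a - al) / 65536
    bl <- b %% 65536; bh <- (b - bl) / 65536
    bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
      bitwXor(as.integer(al), as.integer(bl))
  }
  mul32 <- function(a, b) {
    al <- a %% 65536; ah <- (a - al) / 65536
    (((ah * b) %% 65536) * 65536 + al * b) %% 4294967296
  }
  s <- as.numeric(seed) %% 4294967296
  bytes <- c(utf8ToInt(label),
             s %% 256, (s %/% 256) %% 256,
             (s %/% 65536) %% 256, (s %/% 16777216) %% 256)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b %% 256)
    h <- mul32(h, 16777619)
  }
  as.integer(h %% 2147483647)
}
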