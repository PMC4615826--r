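#' Coupled linear autoregressive pair with known directed coupling
#'
#' Generates a benchmark pair with strictly unidirectional coupling
#' `y -> x`: `y` is AR(1) with coefficient `b`, and
#' `x_t = a x_{t-1} + c y_{t-lag} + e_t`. On this linear-Gaussian
#' fixture the transfer entropy in nats equals half the Granger
#' causality, which makes the pair an exact oracle for estimator
#' validation.
#'
#' @param n Number of samples returned per series (>= 1000).
#' @param a,b AR(1) coefficients of `x` and `y` (|a|, |b| < 1).
#' @param c_coef Coupling coefficient from `y` into `x` (0 = independent).
#' @param lag Coupling lag in samples (>= 1).
#' @param noise_sd Innovation standard deviation of both series.
#' @param seed Integer seed; generation is reproducible.
#' @param noise_seeds Optional pair of seeds for the two innovation
#'   streams (defaults derived from `seed`); passing the same seed
#'   twice with `c_coef = 0` and `a == b` yields identical series.
#' @param burn Burn-in samples discarded (default 500).
#' @return List with numeric vectors `x` and `y`.
#' @export
gen_coupled_pair <- function(n, a = 0.5, b = 0.5, c_coef = 0.5, lag = 1L,
                             noise_sd = 1, seed = 1L, noise_seeds = NULL,
                             burn = 500L) {
  if (abs(a) >= 1 || abs(b) >= 1) stop("non-stationary AR coefficient (|a|,|b| must be < 1)")
  if (n < 1000L) stop("'n' must be >= 1000")
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be >= 1")
  if (is.null(noise_seeds)) {
    noise_seeds <- c(derive_seed(seed, "noise_y"), derive_seed(seed, "noise_x"))
  }
  nt <- n + burn
  ey <- withr_seed(noise_seeds[1], stats::rnorm(nt, sd = noise_sd))
  ex <- withr_seed(noise_seeds[2], stats::rnorm(nt, sd = noise_sd))
  y <- as.numeric(stats::filter(ey, b, method = "recursive"))
  y_lagged <- c(rep(0, lag), y[seq_len(nt - lag)])
  x <- as.numeric(stats::filter(ex + c_coef * y_lagged, a, method = "recursive"))
  keep <- (burn + 1L):nt
  list(x = x[keep], y = y[keep])
}

#' Quadratically coupled pair: invisible to linear measures
#'
#' Generates `y` as a zero-mean AR(1) process and
#' `x_t = a x_{t-1} + c y_{t-lag}^2 + e_t`. Because `y` is symmetric
#' about zero, the linear cross-correlation between `x_t` and
#' `y_{t-lag}` vanishes while the information transfer `y -> x` is
#' positive: the fixture separates model-free transfer entropy from
#' linear Granger causality.
#'
#' @inheritParams gen_coupled_pair
#' @export
gen_nonlinear_pair <- function(n, c_coef = 0.8, lag = 1L, seed = 1L,
                               a = 0.5, b = 0.5, noise_sd = 1, burn = 500L) {
  if (abs(a) >= 1 || abs(b) >= 1) stop("non-stationary AR coefficient (|a|,|b| must be < 1)")
  if (n < 1000L) stop("'n' must be >= 1000")
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be >= 1")
  nt <- n + burn
  ey <- withr_seed(derive_seed(seed, "nl_noise_y"), stats::rnorm(nt, sd = noise_sd))
  ex <- withr_seed(derive_seed(seed, "nl_noise_x"), stats::rnorm(nt, sd = noise_sd))
  y <- as.numeric(stats::filter(ey, b, method = "recursive"))
  y_lagged <- c(rep(0, lag), y[seq_len(nt - lag)])
  x <- as.numeric(stats::filter(ex + c_coef * y_lagged^2, a, method = "recursive"))
  keep <- (burn + 1L):nt
  list(x = x[keep], y = y[keep])
}

#' Ground-truth coupling between two channels
#'
#' Describes one directed coupling of the synthetic session generator:
#' a dedicated band-limited source is added to the source channel and
#' mixed, `lag` samples later, into the sink channel with a
#' coefficient given by `strength_profile(DP)` evaluated at each
#' trial's ground-truth driving-performance index.
#'
#' Profile shapes: `constant` (coefficient `strength` everywhere),
#' `inverted_u` (Gaussian bump peaking at `peak_dp`, default 2.5, with
#' width `width` DP units) and `monotone_decreasing` (linear decline
#' from `strength` at DP 1 to `strength * floor_frac` at DP 4).
#'
#' @param source,sink Channel labels.
#' @param lag Coupling lag in samples at the generation rate (>= 1).
#' @param shape One of `"constant"`, `"inverted_u"`,
#'   `"monotone_decreasing"`.
#' @param strength Peak coupling coefficient (dimensionless).
#' @param peak_dp Location of the inverted-U maximum in DP units.
#' @param width Standard deviation of the inverted-U bump (DP units).
#' @param floor_frac Terminal fraction of the monotone decline at DP 4.
#' @return An object of class `coupling_truth` whose
#'   `$strength_profile` is a function of DP in `[1, 4]`.
#' @export
coupling_truth <- function(source, sink, lag = 2L,
                           shape = c("inverted_u", "monotone_decreasing",
                                     "constant"),
                           strength = 1, peak_dp = 2.5, width = 0.5,
                           floor_frac = 0.1) {
  shape <- match.arg(shape)
  lag <- as.integer(lag)
  stopifnot(lag >= 1L, strength >= 0, width > 0,
            floor_frac >= 0, floor_frac <= 1)
  profile <- switch(shape,
    constant = local({ s <- strength; function(dp) rep(s, length(dp)) }),
    inverted_u = local({
      s <- strength; p <- peak_dp; w <- width
      function(dp) s * exp(-(dp - p)^2 / (2 * w^2))
    }),
    monotone_decreasing = local({
      s <- strength; f <- floor_frac
      function(dp) s * (1 - (1 - f) * pmin(pmax(dp - 1, 0), 3) / 3)
    }))
  structure(list(source = source, sink = sink, lag = lag, shape = shape,
                 strength = strength, peak_dp = peak_dp, width = width,
                 floor_frac = floor_frac, strength_profile = profile),
            class = "coupling_truth")
}

#' Vigilance trajectory helpers
#'
#' `vigilance_decline()` returns a trajectory function (trial index,
#' number of trials) -> latent vigilance in `[0, 1]` that declines
#' smoothly from `v_start` to `v_end` over the session, emulating the
#' drift from alertness into drowsiness across a monotonous drive.
#' `vigilance_constant()` holds vigilance fixed.
#'
#' @param v_start,v_end Vigilance at the first and last trial.
#' @param shape Exponent of the decline (1 = linear; > 1 declines
#'   slowly at first).
#' @param level Constant vigilance level.
#' @return A function `f(i, n_trials)`.
#' @export
vigilance_decline <- function(v_start = 1, v_end = 0.05, shape = 1.2) {
  force(v_start); force(v_end); force(shape)
  function(i, n_trials) {
    frac <- if (n_trials > 1L) (i - 1) / (n_trials - 1) else 0
    pmin(pmax(v_start + (v_end - v_start) * frac^shape, 0), 1)
  }
}

#' @rdname vigilance_decline
#' @export
vigilance_constant <- function(level = 1) {
  force(level)
  function(i, n_trials) rep(pmin(pmax(level, 0), 1), length(i))
}

#' Session generator configuration
#'
#' Study-condition parameters of the synthetic sustained-attention
#' driving session: trial count, generation sampling rate (500 Hz,
#' later decimated to 250 Hz by the preprocessing stage), 1-s baseline
#' epoch, inter-trial interval uniform in 5-10 s, the latent vigilance
#' trajectory, and the lognormal reaction-time noise scale.
#'
#' @param n_trials Number of lane-departure trials (>= 1).
#' @param fs Generation sampling rate in Hz (default 500).
#' @param epoch_len Baseline epoch length in seconds (default 1);
#'   `epoch_len * fs` must be an integer.
#' @param iti_range Inter-trial interval range in seconds (default 5-10).
#' @param vigilance_trajectory Function (trial index, n_trials) ->
#'   vigilance in `[0, 1]`; default [vigilance_decline()].
#' @param rt_noise Lognormal sigma of the reaction-time model.
#' @param seed Integer seed; all randomness in the session flows from it.
#' @param channels Channel labels; must include Fz, Cz, C3, C4, Pz, Oz.
#' @param max_response_record Cap, in seconds, on the post-onset
#'   segment written into the continuous record (the full reaction
#'   time, possibly hundreds of seconds during a lapse, is kept in the
#'   behavioral table; only the 1-s pre-onset baseline is analyzed).
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_trials, fs = 500, epoch_len = 1,
                           iti_range = c(5, 10),
                           vigilance_trajectory = vigilance_decline(),
                           rt_noise = 0.2, seed = 1L,
                           channels = c("Fz", "Cz", "C3", "C4", "Pz", "Oz"),
                           max_response_record = 6) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  if (abs(epoch_len * fs - round(epoch_len * fs)) > 1e-9) {
    stop("'epoch_len' times 'fs' must be an integer sample count")
  }
  required <- c("Fz", "Cz", "C3", "C4", "Pz", "Oz")
  miss <- setdiff(required, channels)
  if (length(miss)) stop("missing required channel labels: ", paste(miss, collapse = ", "))
  stopifnot(length(iti_range) == 2L, iti_range[1] > 0,
            iti_range[2] >= iti_range[1], is.function(vigilance_trajectory),
            rt_noise >= 0, max_response_record > 0)
  structure(list(n_trials = n_trials, fs = fs, epoch_len = epoch_len,
                 iti_range = iti_range,
                 vigilance_trajectory = vigilance_trajectory,
                 rt_noise = rt_noise, seed = as.integer(seed),
                 channels = channels,
                 max_response_record = max_response_record),
            class = "session_config")
}

# vigilance-dependent band mixing weights: delta/theta power rises and
# alpha/beta power falls as vigilance declines
.band_weights <- function(v) {
  cbind(delta = 0.5 + 1.5 * (1 - v),
        theta = 0.6 + 0.8 * (1 - v),
        alpha = 1.5 - 1.1 * (1 - v),
        beta  = 1.0 - 0.6 * (1 - v))
}

# unit-variance band-limited noise (4th-order Butterworth band-pass)
.band_noise <- function(n, lo, hi, fs) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  z <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  z / stats::sd(z)
}

#' Generate a synthetic drowsy-driving session
#'
#' Produces a continuous multichannel record plus per-trial behavior
#' with fully known ground truth. Reaction times follow a lognormal
#' model whose median grows as latent vigilance falls, with a rare
#' heavy-tailed lapse component (RT uniform in 10-300 s) whose
#' probability rises in deep drowsiness. Each channel mixes
#' band-limited delta/theta/alpha/beta sources whose weights shift
#' with vigilance (slow power up, fast power down when drowsy).
#' Directed couplings follow each [coupling_truth()]: a dedicated
#' band-limited source enters the source channel and, `lag` samples
#' later, the sink channel scaled by `strength_profile(DP)`, where the
#' trial's ground-truth DP is computed from the generated reaction
#' times through the behavior module itself.
#'
#' @param config A [session_config()].
#' @param truths List of [coupling_truth()] objects (may be empty).
#' @return A list with elements `session` (class `eeg_session`:
#'   channels-by-samples matrix `data`, `fs`, `channels`,
#'   `onset_sample`, `onset_s`, `rt_s`, `vigilance`, `weights`
#'   (n_trials x 4 band mixing weights), `coupling` (n_trials x
#'   n_truths coefficients), `truths`, `config`, `seed`) and
#'   `behavior` (the [trial_behavior()] data frame).
#' @export
gen_session <- function(config, truths = list()) {
  stopifnot(inherits(config, "session_config"))
  if (inherits(truths, "coupling_truth")) truths <- list(truths)
  for (tr in truths) {
    stopifnot(inherits(tr, "coupling_truth"))
    miss <- setdiff(c(tr$source, tr$sink), config$channels)
    if (length(miss)) stop("coupling references unknown channel(s): ",
                           paste(miss, collapse = ", "))
  }
  N <- config$n_trials; fs <- config$fs
  withr_seed(config$seed, {
    v <- pmin(pmax(config$vigilance_trajectory(seq_len(N), N), 0), 1)
    # reaction-time model: lognormal with vigilance-dependent location,
    # plus lapses
    z <- stats::rnorm(N)
    rt <- exp(log(0.75) + 2.1 * (1 - v) + config$rt_noise * z)
    lapse <- stats::runif(N) < 0.15 * (1 - v)^2
    if (any(lapse)) rt[lapse] <- stats::runif(sum(lapse), 10, 300)
    behavior <- trial_behavior(rt)
    # timeline: [iti][onset][recorded response segment] per trial
    iti <- stats::runif(N, config$iti_range[1], config$iti_range[2])
    resp <- pmin(rt, config$max_response_record)
    iti_n <- as.integer(round(iti * fs))
    resp_n <- as.integer(round(resp * fs))
    block_n <- iti_n + resp_n
    onset_sample <- cumsum(c(0L, block_n[-N])) + iti_n + 1L
    # 2 s tail after the last trial keeps its baseline epoch clear of
    # filter edge transients
    block_n[N] <- block_n[N] + 2L * as.integer(fs)
    n_tot <- sum(block_n)
    per_sample_trial <- rep.int(seq_len(N), block_n)

    bands <- list(delta = c(1, 4), theta = c(5, 7), alpha = c(8, 12),
                  beta = c(13, 20))
    W <- .band_weights(v)
    nch <- length(config$channels)
    data <- matrix(0, nch, n_tot)
    rownames(data) <- config$channels
    for (ch in seq_len(nch)) {
      acc <- 0.3 * stats::rnorm(n_tot)
      for (b in seq_along(bands)) {
        w_vec <- W[per_sample_trial, b]
        acc <- acc + w_vec * .band_noise(n_tot, bands[[b]][1], bands[[b]][2], fs)
      }
      data[ch, ] <- acc
    }
    coupling <- matrix(0, N, length(truths))
    for (j in seq_along(truths)) {
      tr <- truths[[j]]
      # broadband (4-40 Hz) shared source, amplitude 2 relative to the
      # unit-sd background bands: the transferred signal must carry
      # innovations the sink's own past cannot predict, otherwise the
      # conditional information transfer of a narrowband oscillation is
      # nearly zero however strong the mixing
      g <- 2 * .band_noise(n_tot, 4, 40, fs)
      ci <- tr$strength_profile(behavior$dp)
      coupling[, j] <- ci
      c_vec <- ci[per_sample_trial]
      g_lag <- c(rep(0, tr$lag), g[seq_len(n_tot - tr$lag)])
      data[tr$source, ] <- data[tr$source, ] + g
      data[tr$sink, ] <- data[tr$sink, ] + c_vec * g_lag
    }
    session <- structure(list(data = data, fs = fs,
                              channels = config$channels,
                              onset_sample = onset_sample,
                              onset_s = (onset_sample - 1L) / fs,
                              rt_s = rt, vigilance = v, weights = W,
                              coupling = coupling, truths = truths,
                              config = config, seed = config$seed),
                         class = "eeg_session")
    list(session = session, behavior = behavior)
  })
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("eeg_session: %d channels x %d samples @ %g Hz, %d trials, %d coupling truth(s)\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$onset_sample),
              length(x$truths)))
  invisible(x)
}

#' Simulate a multi-subject study
#'
#' Convenience wrapper generating one session per subject with
#' subject-specific seeds derived from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject.
#' @param truths List of [coupling_truth()] objects shared by all
#'   subjects.
#' @param seed Study-level seed.
#' @param ... Further arguments passed to [session_config()].
#' @return List of `gen_session()` results, one per subject.
#' @export
simulate_study <- function(n_subjects, n_trials, truths = list(), seed = 1L,
                           ...) {
  lapply(seq_len(n_subjects), function(s) {
    cfg <- session_config(n_trials = n_trials,
                          seed = derive_seed(seed, paste0("subject", s)), ...)
    gen_session(cfg, truths)
  })
}
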