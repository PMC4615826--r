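#' Band-pass filter specification
#'
#' Windowed-sinc FIR band-pass design applied forward-backward
#' (zero-phase). The default order follows the common EEG toolbox
#' heuristic of `3 * fs / low_cut` taps, rounded up to an even number.
#'
#' @param low_cut,high_cut Pass-band edges in Hz (0 < low < high < fs/2).
#' @param order Optional FIR order override (even; default the
#'   heuristic above, resolved when the filter is applied).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 1, high_cut = 50, order = NULL) {
  stopifnot(low_cut > 0, high_cut > low_cut)
  if (!is.null(order)) {
    order <- as.integer(order)
    stopifnot(order >= 2L)
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order),
            class = "filter_spec")
}

.resolve_fir_order <- function(spec, fs) {
  ord <- spec$order
  if (is.null(ord)) ord <- as.integer(round(3 * fs / spec$low_cut))
  if (ord %% 2L == 1L) ord <- ord + 1L
  ord
}

#' Zero-phase FIR band-pass filtering
#'
#' Filters a sampled series with a windowed-sinc (Hamming) FIR
#' band-pass applied forward and backward, so the net group delay is
#' zero and in-band components stay phase-aligned with the input.
#' Output length equals input length; edges are stabilized by odd
#' reflection padding.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()]; the default is the 1-50 Hz EEG
#'   band-pass.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_cut >= fs / 2) stop("high_cut must be below the Nyquist frequency")
  ord <- .resolve_fir_order(spec, fs)
  n <- length(x)
  if (n <= 3L * ord) {
    stop("signal too short for the designed filter order (need > ", 3L * ord,
         " samples); lower the order or raise low_cut")
  }
  b <- signal::fir1(ord, c(spec$low_cut, spec$high_cut) / (fs / 2),
                    type = "pass")
  .filtfilt_fir(x, b)
}

# forward-backward FIR filtering with odd reflection padding; `b` must
# be linear phase with even order (delay ord/2 is an integer)
.filtfilt_fir <- function(x, b) {
  n <- length(x)
  nb <- length(b)
  delay <- (nb - 1L) %/% 2L
  pad <- min(n - 1L, 3L * (nb - 1L))
  xe <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  one_pass <- function(z) {
    L <- stats::nextn(length(z) + nb - 1L, 2)
    conv <- Re(stats::fft(stats::fft(c(z, numeric(L - length(z)))) *
                          stats::fft(c(b, numeric(L - nb))), inverse = TRUE)) / L
    conv[(delay + 1L):(delay + length(z))]
  }
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Frequency response magnitude of the band-pass design
#'
#' Squared (forward-backward) magnitude response of the FIR band-pass
#' that [bandpass_zero_phase()] would apply, evaluated at the given
#' frequencies. Useful for checking stop-band attenuation.
#'
#' @inheritParams bandpass_zero_phase
#' @param freqs Frequencies in Hz.
#' @return Magnitude (linear scale) of the effective two-pass filter.
#' @export
bandpass_response <- function(freqs, fs, spec = filter_spec()) {
  ord <- .resolve_fir_order(spec, fs)
  b <- signal::fir1(ord, c(spec$low_cut, spec$high_cut) / (fs / 2),
                    type = "pass")
  k <- seq_along(b) - 1L
  vapply(freqs, function(f) {
    Mod(sum(b * exp(-2i * pi * f * k / fs)))^2
  }, numeric(1))
}

#' Integer-factor downsampling
#'
#' Keeps every `factor`-th sample starting at the first, where
#' `factor = fs_in / fs_out` must be an integer; the input is assumed
#' to be low-passed below `fs_out / 2` already (see
#' [bandpass_zero_phase()]).
#'
#' @param x Numeric series.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Decimated series of length `ceiling(length(x) / factor)`;
#'   output sample `k` (0-based) equals input sample `k * factor`.
#' @export
downsample <- function(x, fs_in, fs_out) {
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9) {
    stop("non-integer decimation factor (", fs_in, " / ", fs_out, ")")
  }
  x[seq(1L, length(x), by = as.integer(round(factor)))]
}

#' Filter and downsample a continuous session
#'
#' Applies the zero-phase band-pass to every channel and decimates the
#' record to `fs_target`, updating the stored deviation-onset sample
#' indices (onset times in seconds are preserved).
#'
#' @param session An `eeg_session` (see [gen_session()]).
#' @param spec A [filter_spec()].
#' @param fs_target Target sampling rate in Hz (default 250).
#' @return The preprocessed `eeg_session`.
#' @export
preprocess_session <- function(session, spec = filter_spec(),
                               fs_target = 250) {
  stopifnot(inherits(session, "eeg_session"))
  factor <- session$fs / fs_target
  if (abs(factor - round(factor)) > 1e-9) stop("non-integer decimation factor")
  factor <- as.integer(round(factor))
  data <- t(apply(session$data, 1, function(ch) {
    downsample(bandpass_zero_phase(ch, session$fs, spec), session$fs, fs_target)
  }))
  rownames(data) <- session$channels
  out <- session
  out$data <- data
  out$fs <- fs_target
  # decimated sample at or immediately before each original onset
  out$onset_sample <- as.integer((session$onset_sample - 1L) %/% factor + 1L)
  out
}

#' Extract 1-s baseline epochs preceding each deviation onset
#'
#' Cuts, for every trial, the half-open window `[onset - epoch_len,
#' onset)` from the continuous record: the epoch ends one sample
#' before the deviation onset and never reads samples at or after it.
#' Trials whose onset is too close to the start of the recording are
#' dropped with a warning.
#'
#' @param session An `eeg_session`, normally already preprocessed.
#' @param epoch_len Epoch length in seconds (default 1).
#' @return An object of class `eeg_epochs`: a 3-d array
#'   channels x trials x samples with attributes `channels`, `fs` and
#'   `trial_index` (indices into the session's trial list of the
#'   epochs kept).
#' @export
extract_baseline_epochs <- function(session, epoch_len = 1) {
  stopifnot(inherits(session, "eeg_session"))
  ns <- epoch_len * session$fs
  if (abs(ns - round(ns)) > 1e-9) stop("non-integer epoch sample count")
  ns <- as.integer(round(ns))
  onset <- session$onset_sample
  keep <- which(onset - ns >= 1L)
  if (length(keep) < length(onset)) {
    warning(length(onset) - length(keep),
            " trial(s) dropped: onset within ", epoch_len,
            " s of recording start")
  }
  nch <- nrow(session$data)
  out <- array(0, dim = c(nch, length(keep), ns))
  for (i in seq_along(keep)) {
    o <- onset[keep[i]]
    out[, i, ] <- session$data[, (o - ns):(o - 1L), drop = FALSE]
  }
  structure(out, channels = session$channels, fs = session$fs,
            trial_index = keep, class = "eeg_epochs")
}

#' Epoch matrix for one channel
#'
#' @param epochs An `eeg_epochs` array.
#' @param channel Channel label or index.
#' @return Trials-by-samples matrix for that channel.
#' @export
channel_epochs <- function(epochs, channel) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.character(channel)) {
    channel <- match(channel, attr(epochs, "channels"))
    if (is.na(channel)) stop("unknown channel label")
  }
  matrix(epochs[channel, , ], nrow = dim(epochs)[2])
}

#' Time-shift screen for instantaneous mixing
#'
#' Screens an ordered channel pair for instantaneous (zero-lag) mixing
#' such as volume conduction: the transfer entropy from the source
#' shifted one sample into the future is compared, trial by trial,
#' with the unshifted estimate. Under instantaneous mixing the shifted
#' source predicts the sink better, so a significant positive mean
#' difference rejects the pair. Significance is assessed by a
#' one-sided sign-flip permutation test over trials.
#'
#' @param source_epochs,sink_epochs Trials-by-samples matrices (see
#'   [channel_epochs()]); single trials may be given as vectors.
#' @param spec An [embedding_spec()].
#' @param n_perm Number of sign-flip permutations (default 200).
#' @param alpha Rejection level (default 0.05).
#' @param seed Seed for the permutation draw.
#' @return List with `pass` (logical: `TRUE` means no instantaneous
#'   mixing detected), `p_value`, `mean_diff` (bits) and the per-trial
#'   TE values for the shifted and unshifted source.
#' @export
time_shift_test <- function(source_epochs, sink_epochs,
                            spec = embedding_spec(), n_perm = 200L,
                            alpha = 0.05, seed = 1L) {
  if (!is.matrix(source_epochs)) source_epochs <- matrix(source_epochs, 1)
  if (!is.matrix(sink_epochs)) sink_epochs <- matrix(sink_epochs, 1)
  if (!all(dim(source_epochs) == dim(sink_epochs))) {
    stop("source and sink epochs must have identical shape")
  }
  nt <- nrow(source_epochs)
  te_orig <- te_shift <- numeric(nt)
  for (i in seq_len(nt)) {
    src <- source_epochs[i, ]
    snk <- sink_epochs[i, ]
    # drop the last sample so shifted and unshifted use equal lengths
    src_shift <- src[-1]
    te_orig[i] <- ksg_te(src[-length(src)], snk[-length(snk)], spec)$te_bits
    te_shift[i] <- ksg_te(src_shift, snk[-length(snk)], spec)$te_bits
  }
  d <- te_shift - te_orig
  obs <- mean(d)
  if (nt == 1L) {
    # single trial: no permutation distribution over trials; fall back
    # to a conservative sign test on the one difference
    p <- if (obs > 0) 0.5 else 1
  } else {
    null_means <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        mean(d * sample(c(-1, 1), nt, replace = TRUE))
      }, numeric(1))
    })
    p <- (1 + sum(null_means >= obs)) / (1 + n_perm)
  }
  list(pass = p >= alpha, p_value = p, mean_diff = obs,
       te_shifted = te_shift, te_unshifted = te_orig)
}
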