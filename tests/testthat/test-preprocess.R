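test_that("band-pass is zero-phase and meets the attenuation contract", {
  fs <- 500
  t <- (0:(fs * 12 - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_zero_phase(x, fs)
  cc <- stats::ccf(y, x, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_gt(max(cc$acf), 0.999)
  # DC is far below the 1 Hz pass-band edge
  expect_lt(abs(mean(bandpass_zero_phase(x + 5, fs))), 0.01)
  # designed two-pass response: >= 40 dB down at 0.5x low and 1.5x high cut
  resp_db <- 20 * log10(bandpass_response(c(0.5, 75), fs))
  expect_true(all(resp_db <= -40))
  # 60 Hz steady-state residual (outside filter edge transients) < 1% RMS
  x60 <- sin(2 * pi * 60 * t)
  y60 <- bandpass_zero_phase(x60, fs)
  mid <- (fs * 4):(fs * 8)
  expect_lt(sqrt(mean(y60[mid]^2)) / sqrt(mean(x60^2)), 0.01)
  expect_error(bandpass_zero_phase(rnorm(100), fs), "too short")
  expect_error(bandpass_zero_phase(x, fs, filter_spec(1, 300)), "Nyquist")
})

test_that("downsampling decimates from the first sample", {
  x <- rnorm(1000)
  y <- downsample(x, 500, 250)
  expect_length(y, 500)
  expect_equal(y[1], x[1])
  expect_equal(y, x[seq(1, 999, by = 2)])
  # a 10 Hz tone stays at 10 Hz after decimation
  fs <- 500
  t <- (0:(fs * 4 - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  dec <- downsample(tone, 500, 250)
  spec <- Mod(stats::fft(dec))[1:(length(dec) / 2)]
  f_axis <- (seq_along(spec) - 1) * 250 / length(dec)
  expect_equal(f_axis[which.max(spec)], 10)
  expect_error(downsample(x, 500, 300), "non-integer")
})

test_that("baseline epochs end one sample before onset and never after", {
  fs <- 250
  data <- matrix(rep(1:(fs * 20), each = 2), nrow = 2, byrow = FALSE)
  ses <- structure(list(data = data, fs = fs, channels = c("A", "B"),
                        onset_sample = c(1L, 100L, 500L, 2000L),
                        rt_s = rep(1, 4)),
                   class = "eeg_session")
  expect_warning(ep <- extract_baseline_epochs(ses), "dropped")
  expect_equal(dim(ep), c(2, 2, 250))
  expect_equal(attr(ep, "trial_index"), c(3L, 4L))
  # epoch holds exactly samples onset-250 .. onset-1 of the record
  expect_equal(ep[1, 1, ], as.numeric(250:499))
  expect_equal(ep[1, 2, ], as.numeric(1750:1999))
  # zero trials: empty epoch set, no error
  ses0 <- ses; ses0$onset_sample <- integer(0); ses0$rt_s <- numeric(0)
  ep0 <- extract_baseline_epochs(ses0)
  expect_equal(dim(ep0), c(2, 0, 250))
})

test_that("filtering the record commutes with epoching a padded window", {
  fs <- 500
  set.seed(77)
  n <- fs * 40
  x <- as.numeric(stats::filter(rnorm(n), 0.8, method = "recursive"))
  spec <- filter_spec(1, 50, order = 500)
  onset <- fs * 20
  full <- bandpass_zero_phase(x, fs, spec)[(onset - fs):(onset - 1)]
  pad <- 4 * 500
  seg <- x[(onset - fs - pad):(onset - 1 + pad)]
  windowed <- bandpass_zero_phase(seg, fs, spec)[(pad + 1):(pad + fs)]
  expect_lt(max(abs(full - windowed)) / stats::sd(full), 1e-6)
})

test_that("time-shift screen flags instantaneous mixing and passes clean pairs", {
  set.seed(88)
  nt <- 25; ns <- 200
  base <- matrix(rnorm(nt * ns), nt, ns)
  sp <- embedding_spec(d = 1, m = 1, tau = 1, u = 1)
  # near-perfect instantaneous copy
  mixed <- base + 0.05 * matrix(rnorm(nt * ns), nt, ns)
  res_mix <- time_shift_test(base, mixed, sp, seed = 1)
  expect_false(res_mix$pass)
  # independent pair
  indep <- matrix(rnorm(nt * ns), nt, ns)
  res_ind <- time_shift_test(base, indep, sp, seed = 2)
  expect_true(res_ind$pass)
  # genuinely lagged coupling must not be rejected
  ses <- small_coupled_session()
  ep <- extract_baseline_epochs(preprocess_session(ses$session))
  res_lag <- time_shift_test(channel_epochs(ep, "Cz"),
                             channel_epochs(ep, "Pz"),
                             embedding_spec(d = 2, m = 2, tau = 1, u = 1),
                             seed = 3)
  expect_true(res_lag$pass)
})
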