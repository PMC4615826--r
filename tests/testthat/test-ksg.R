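spec1 <- embedding_spec(d = 1, m = 1, tau = 1, u = 1)

test_that("independent series carry no measurable transfer entropy", {
  p <- gen_coupled_pair(1e4, c_coef = 0, seed = 21)
  expect_lt(abs(ksg_te(p$y, p$x, spec1)$te_bits), 0.02)
  expect_lt(abs(ksg_te(p$x, p$y, spec1)$te_bits), 0.02)
})

test_that("TE matches GC/(2 ln 2) on linear-Gaussian data, error shrinking with n", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    p <- gen_coupled_pair(n, a = 0.5, b = 0.5, c_coef = 0.5, lag = 1,
                          seed = 33)
    te <- ksg_te(p$y, p$x, spec1)$te_bits
    gc <- granger(p$x, p$y, 1)
    abs(te - gc / (2 * log(2)))
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1])
})

test_that("discretized input reproduces the exact plug-in transfer entropy", {
  py <- c(0.3, 0.8)
  px <- matrix(c(0.2, 0.7, 0.4, 0.9), 2, 2)
  te_exact <- markov_te_exact(py, px)
  sim <- simulate_markov_pair(py, px, n = 2e4, seed = 11)
  # dither below the symbol spacing: the jittered variables determine
  # the symbols, so their conditional mutual information is unchanged
  set.seed(12)
  xj <- sim$x + runif(2e4, 0, 0.25)
  yj <- sim$y + runif(2e4, 0, 0.25)
  te_hat <- ksg_te(yj, xj, spec1)$te_bits
  expect_equal(te_hat, te_exact, tolerance = 0.01 / te_exact)
})

test_that("estimated TE is asymmetric under unidirectional coupling", {
  fwd <- rev <- numeric(20)
  for (i in 1:20) {
    p <- gen_coupled_pair(2000, c_coef = 0.4, lag = 1, seed = 100 + i)
    fwd[i] <- ksg_te(p$y, p$x, spec1)$te_bits
    rev[i] <- ksg_te(p$x, p$y, spec1)$te_bits
  }
  expect_gt(median(fwd), median(rev))
  expect_gt(mean(fwd > rev), 0.8)
})

test_that("Theiler exclusion changes the estimate smoothly", {
  p <- gen_coupled_pair(3000, c_coef = 0.5, seed = 55)
  te <- vapply(0:3, function(T) {
    sp <- spec1; sp$theiler <- T
    ksg_te(p$y, p$x, sp)$te_bits
  }, numeric(1))
  expect_true(all(is.finite(te)))
  expect_lt(max(abs(diff(te))), 0.05)
})

test_that("TE is invariant to separate affine rescaling of the series", {
  p <- gen_coupled_pair(3000, c_coef = 0.5, seed = 56)
  base <- ksg_te(p$y, p$x, spec1)$te_bits
  # exact up to floating-point tie flips in the internal z-scoring
  expect_equal(ksg_te(5 * p$y - 2, 0.1 * p$x + 40, spec1)$te_bits, base,
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  p <- gen_coupled_pair(2000, seed = 57)
  expect_error(ksg_te(p$y, rep(1, 2000), spec1), "zero-variance")
  bad <- p$x; bad[5] <- NA
  expect_error(ksg_te(p$y, bad, spec1), "NaN|NA")
  expect_error(ksg_te(p$y[1:5], p$x[1:5], spec1), "too short")
  expect_error(ksg_te(p$y[1:100], p$x, spec1), "length")
})

test_that("prediction-time conversion rounds half up with a one-sample floor", {
  expect_equal(ms_to_samples(c(5, 10, 20, 40, 60, 80, 100), 250),
               c(1L, 3L, 5L, 10L, 15L, 20L, 25L))
  expect_equal(ms_to_samples(1, 250), 1L)
})

test_that("prediction-time search recovers the true coupling lag", {
  p <- gen_coupled_pair(6000, c_coef = 0.8, lag = 10, seed = 60)
  # candidates 4/20/40 ms at 250 Hz are 1, 5, 10 samples
  sel <- select_u(p$y, p$x, spec1, candidates_ms = c(4, 20, 40), fs = 250)
  expect_equal(sel$u, 10L)
  expect_equal(unname(which.max(sel$te_bits)), 3L)
  one <- select_u(p$y, p$x, spec1, candidates_ms = 40, fs = 250)
  expect_equal(one$u, 10L)
  expect_error(select_u(p$y, p$x, spec1, candidates_ms = numeric(0)),
               "empty")
})

test_that("surrogate test detects strong coupling and respects its floor", {
  p <- gen_coupled_pair(5000, c_coef = 0.8, lag = 1, seed = 61)
  st <- surrogate_test(p$y, p$x, spec1, n_perm = 199, seed = 62)
  expect_lte(st$p_value, 0.01)
  q <- gen_coupled_pair(5000, c_coef = 0, seed = 63)
  st0 <- surrogate_test(q$y, q$x, spec1, n_perm = 99, seed = 64)
  expect_gt(st0$p_value, 0.05)
  expect_error(surrogate_test(p$y, p$x, spec1, n_perm = 0), "n_perm")
})

test_that("pooled multi-trial estimation detects coupling across epochs", {
  ses <- small_coupled_session()
  pre <- preprocess_session(ses$session)
  ep <- extract_baseline_epochs(pre)
  src <- channel_epochs(ep, "Cz")
  snk <- channel_epochs(ep, "Pz")
  sp <- embedding_spec(d = 2, m = 2, tau = 1, u = 1)
  te_fwd <- ksg_te(src, snk, sp)
  te_rev <- ksg_te(snk, src, sp)
  expect_gt(te_fwd$te_bits, te_rev$te_bits)
  expect_gt(te_fwd$te_bits, 0.02)
  expect_equal(te_fwd$n_trials, nrow(src))
})
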