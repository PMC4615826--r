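test_that("BIC selects the generating VAR order", {
  # simulate a bivariate VAR(2)
  sim_var2 <- function(n, seed) {
    set.seed(seed)
    x <- y <- numeric(n)
    for (t in 3:n) {
      x[t] <- 0.5 * x[t - 1] - 0.3 * x[t - 2] + 0.3 * y[t - 2] + rnorm(1)
      y[t] <- 0.4 * y[t - 1] + 0.25 * y[t - 2] + rnorm(1)
    }
    list(x = x, y = y)
  }
  hits <- vapply(1:10, function(i) {
    s <- sim_var2(4000, 200 + i)
    fit_var_order_bic(s$x, s$y, p_max = 6)
  }, integer(1))
  expect_gte(mean(hits == 2L), 0.9)
  s <- sim_var2(4000, 199)
  expect_equal(fit_var_order_bic(s$x, s$y, p_max = 1), 1L)
  expect_error(fit_var_order_bic(rep(1, 4000), s$y, 4), "constant")
  expect_error(fit_var_order_bic(s$x[1:30], s$y[1:30], 6), "too short")
})

test_that("Granger causality matches the population value of the generating model", {
  p <- gen_coupled_pair(5e4, a = 0.5, b = 0.5, c_coef = 0.5, lag = 1,
                        seed = 44)
  gc_hat <- granger(p$x, p$y, 1)
  gc_pop <- pop_gc_coupled(0.5, 0.5, 0.5)
  expect_equal(gc_hat, gc_pop, tolerance = 0.05)
  # no reverse-direction causality in the unidirectional fixture
  expect_lt(granger(p$y, p$x, 1), 0.003)
  # independent pair: GC at its sampling floor
  q <- gen_coupled_pair(2e4, c_coef = 0, seed = 45)
  expect_lt(granger(q$x, q$y, 1), 0.005)
  expect_gte(granger(q$x, q$y, 1), 0)
  # invariance to separate rescaling
  expect_equal(granger(5 * p$x, 0.2 * p$y, 1), gc_hat, tolerance = 1e-8)
  d <- granger(p$x, p$y, 1, details = TRUE)
  expect_lt(d$p_value, 1e-10)
})

test_that("band power sums the periodogram over inclusive band edges", {
  fs <- 250
  t <- (0:249) / fs
  bands <- eeg_bands()
  alpha <- bands[bands$name == "alpha", ]
  tone <- sin(2 * pi * 10 * t)
  by_band <- vapply(seq_len(nrow(bands)), function(i) {
    band_power(tone, fs, bands[i, ])
  }, numeric(1))
  names(by_band) <- bands$name
  expect_equal(by_band[["alpha"]], 0.5, tolerance = 1e-6)
  expect_gt(by_band[["alpha"]] / sum(by_band), 0.99)
  expect_equal(band_power(rep(0, 250), fs, alpha), 0)
  expect_error(band_power(tone, fs, list(lo = 100, hi = 130)), "Nyquist")
  # flat spectrum: expected power proportional to bin count (5 alpha / 4 delta)
  set.seed(31)
  pw <- replicate(200, {
    z <- rnorm(250)
    c(band_power(z, fs, alpha),
      band_power(z, fs, bands[bands$name == "delta", ]))
  })
  expect_equal(mean(pw[1, ]) / mean(pw[2, ]), 5 / 4, tolerance = 0.1)
  # additivity: the four disjoint bands plus uncovered 1-20 Hz bins
  z <- rnorm(250)
  total_1_20 <- band_power(z, fs, list(lo = 1, hi = 20))
  covered <- sum(vapply(seq_len(nrow(bands)), function(i) {
    band_power(z, fs, bands[i, ])
  }, numeric(1)))
  expect_equal(total_1_20, covered, tolerance = 1e-10)
})

test_that("band-power/DP correlation behaves like Pearson's r", {
  dps <- c(1.1, 1.5, 2.2, 2.9, 3.4)
  expect_equal(band_dp_correlation(dps, dps), 1)
  expect_lt(band_dp_correlation(rev(dps), dps), 0)
  expect_error(band_dp_correlation(rep(1, 5), dps), "zero variance")
  expect_error(band_dp_correlation(dps[1:2], dps[1:2]), "3 trials")
})

test_that("GC and TE rank coupling strengths the same way", {
  cs <- seq(0.1, 0.8, by = 0.1)
  sp <- embedding_spec(d = 1, m = 1, tau = 1, u = 1)
  te <- gc <- numeric(length(cs))
  for (i in seq_along(cs)) {
    p <- gen_coupled_pair(4000, c_coef = cs[i], lag = 1, seed = 400 + i)
    te[i] <- ksg_te(p$y, p$x, sp)$te_bits
    gc[i] <- granger(p$x, p$y, 1)
  }
  expect_gt(cor(te, gc, method = "spearman"), 0.9)
})
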