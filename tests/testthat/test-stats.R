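test_that("relative TE centers on the baseline trials", {
  expect_equal(relative_te(c(1, 2, 3, 4), c(1, 2)), c(-0.5, 0.5, 1.5, 2.5))
  out <- relative_te(rnorm(20), 1:20)
  expect_equal(sum(out), 0, tolerance = 1e-12)
  expect_equal(relative_te(rep(3, 8), c(2, 5)), rep(0, 8))
  expect_error(relative_te(1:4, integer(0)), "empty")
  expect_error(relative_te(1:4, 7), "out of range")
})

test_that("DP windows tile [1, 4] with 26 overlapping windows", {
  set.seed(15)
  dps <- runif(400, 1, 4)
  vals <- rnorm(400)
  prof <- dp_windows(dps, vals)
  expect_equal(nrow(prof), 26)
  expect_equal(prof$window_lo[1], 1.0)
  expect_equal(prof$window_hi[1], 1.5)
  expect_equal(prof$window_lo[26], 3.5)
  expect_equal(prof$window_hi[26], 4.0)
  # membership is half-open except the final window
  prof_edge <- dp_windows(c(1.5, 4.0), c(10, 20))
  members <- attr(prof_edge, "members")
  expect_false(10 %in% members[[1]])   # 1.5 not in [1.0, 1.5)
  expect_true(10 %in% members[[6]])    # [1.5, 2.0)
  expect_true(20 %in% members[[26]])   # 4.0 closed in the last window
  # a single DP value populates exactly the windows covering it
  prof12 <- dp_windows(rep(1.2, 5), rnorm(5))
  expect_equal(which(prof12$n > 0), 1:3)  # [0.8,1.3],[0.9,1.4],[1.0,1.5] starts 1.0-1.2
  expect_true(all(is.na(prof12$mean[prof12$n == 0])))
  # constant values give the constant as every populated mean
  profc <- dp_windows(dps, rep(2.5, 400))
  expect_true(all(abs(profc$mean[profc$n > 0] - 2.5) < 1e-12))
  # empty input: all-missing profile, no error
  prof0 <- dp_windows(numeric(0), numeric(0))
  expect_true(all(prof0$n == 0))
})

test_that("rank-sum tests compare each window with the first", {
  dps <- c(rep(1.2, 50), rep(2.5, 50))
  vals <- c(rnorm(50), rnorm(50) + 10)
  prof <- window_ranksum_vs_first(dp_windows(dps, vals))
  expect_equal(prof$raw_p[1], 1)
  big <- which(prof$n > 0 & prof$window_lo >= 2.05)
  expect_true(all(prof$raw_p[big] < 1e-6, na.rm = TRUE))
  # normal-approximation oracle for the fully separated case
  n1 <- 50; n2 <- 50
  W <- n1 * n2                       # all shifted values rank above
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p_oracle <- 2 * stats::pnorm((W - 0.5 - mu) / sigma, lower.tail = FALSE)
  expect_equal(prof$raw_p[big[1]], p_oracle, tolerance = 1e-6)
  # identical member values give p = 1
  prof_id <- window_ranksum_vs_first(dp_windows(dps, rep(1, 100)))
  expect_true(all(prof_id$raw_p[prof_id$n > 1] == 1))
  # empty first window is an error
  prof_nofirst <- dp_windows(rep(3, 10), rnorm(10))
  expect_error(window_ranksum_vs_first(prof_nofirst), "first window")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(c(0.01, NA, 0.03)), c(0.02, NA, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  set.seed(3)
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # adjusted never below raw, monotone under the step-up rule
  expect_true(all(bh_fdr(p) >= p))
})

test_that("group summaries and listwise/pairwise deletion policies", {
  df <- group_summarize(values = c(1, 1, 1),
                        groups = c("optimal", "sub_optimal", "poor"),
                        subjects = rep("a", 3))
  expect_equal(df$mean, rep(1, 3))
  expect_error(group_summarize(numeric(0), character(0), character(0)),
               "empty")
  # subject b lacks 'poor': dropped from the ANOVA with a warning,
  # kept in the contrasts where both cells exist
  vals <- c(1, 2, 3, 1.2, 2.2, 1.4, 2.5, 3.2)
  grps <- c("optimal", "sub_optimal", "poor",
            "optimal", "sub_optimal",
            "optimal", "sub_optimal", "poor")
  subj <- c("a", "a", "a", "b", "b", "c", "c", "c")
  gs <- group_summarize(vals, grps, subj)
  expect_warning(an <- rm_anova(gs), "dropped")
  expect_equal(an$n_subjects, 2)
  pw <- pairwise_signed_rank(gs)
  expect_equal(pw$n_pairs[pw$contrast == "optimal_vs_sub_optimal"], 3)
  expect_equal(pw$n_pairs[pw$contrast == "sub_optimal_vs_poor"], 2)
})

test_that("repeated-measures ANOVA agrees with the aov() oracle", {
  set.seed(23)
  n <- 9
  df <- expand.grid(subject = sprintf("s%d", 1:n),
                    group = c("optimal", "sub_optimal", "poor"))
  df$mean <- rnorm(nrow(df)) + rep(c(0, 0.8, 0.3), each = n) +
    rep(rnorm(n), 3)
  res <- rm_anova(df)
  fit <- summary(stats::aov(mean ~ group + Error(subject), data = df))
  tab <- fit[["Error: Within"]][[1]]
  expect_equal(res$F, tab["group", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, tab["group", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 2 * (n - 1))
})

test_that("degenerate ANOVA inputs use the stated conventions", {
  df <- expand.grid(subject = c("a", "b", "c"),
                    group = c("optimal", "sub_optimal", "poor"))
  # identical values everywhere: p = 1 with a warning
  df$mean <- 5
  expect_warning(res <- rm_anova(df), "zero error")
  expect_equal(res$p_value, 1)
  # subject offsets but no condition effect: F near 0
  set.seed(8)
  df2 <- expand.grid(subject = sprintf("s%d", 1:6),
                     group = c("optimal", "sub_optimal", "poor"))
  df2$mean <- rep(rnorm(6, sd = 5), 3) + rnorm(18, sd = 0.1)
  res2 <- rm_anova(df2)
  expect_lt(res2$F, 3)
  expect_error(rm_anova(data.frame(subject = "a",
                                   group = c("optimal", "sub_optimal",
                                             "poor"),
                                   mean = 1:3)),
               ">= 2 subjects")
})

test_that("ANOVA detects a consistent within-subject shift", {
  set.seed(77)
  hits <- replicate(200, {
    n <- 12
    df <- expand.grid(subject = sprintf("s%d", 1:n),
                      group = c("optimal", "sub_optimal", "poor"))
    df$mean <- rnorm(nrow(df)) + rep(c(0, 2, 0), each = n) + rep(rnorm(n), 3)
    rm_anova(df)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("pairwise signed-rank tests hit the exact small-sample floor", {
  n <- 12
  df <- expand.grid(subject = sprintf("s%02d", 1:n),
                    group = c("optimal", "sub_optimal", "poor"))
  set.seed(41)
  base <- rnorm(n, sd = 0.2)
  # strictly positive, tie-free shifts: optimal < sub_optimal < poor;
  # any all-positive difference vector attains the exact two-sided
  # signed-rank floor 2 / 2^12
  jit <- seq_len(n) * 1e-3
  df$mean <- rep(base, 3) + rep(c(0, 1, 2), each = n) +
    c(numeric(n), jit, 3 * jit)
  pw <- pairwise_signed_rank(df)
  expect_equal(pw$p_value, rep(2 / 4096, 3), tolerance = 1e-12)
  # identical paired vectors: p = 1
  df$mean <- rep(base, 3)
  pw_id <- pairwise_signed_rank(df)
  expect_equal(pw_id$p_value, rep(1, 3))
  # BH across the three contrasts
  expect_equal(bh_fdr(c(0.01, 1, 1)), c(0.03, 1, 1))
})
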