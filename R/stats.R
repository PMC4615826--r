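#' Baseline-normalized (relative) connectivity values
#'
#' Subtracts the mean over the baseline trials (the subject's best
#' tenth percentile of DP, see [baseline_trial_indices()]) from every
#' trial's value, so subjects are compared on changes from their own
#' alert-state connectivity.
#'
#' @param values Per-trial connectivity values.
#' @param baseline_idx Indices of the baseline trials.
#' @return Values with the baseline mean subtracted; the mean over
#'   `baseline_idx` of the output is zero.
#' @export
relative_te <- function(values, baseline_idx) {
  if (length(baseline_idx) == 0L) stop("empty baseline index set")
  if (any(baseline_idx < 1L) || any(baseline_idx > length(values))) {
    stop("baseline indices out of range")
  }
  values - mean(values[baseline_idx])
}

#' DP-sorted moving windows
#'
#' Groups trials into overlapping DP windows of width `width` moved in
#' steps of `step` across `[lo, hi]` (defaults 0.5 and 0.1 over DP
#' 1-4, giving 26 windows starting with DP 1-1.5). Window membership
#' is half-open `[win_lo, win_hi)` except the final window, which is
#' closed at `hi`. Empty windows carry a missing mean.
#'
#' @param dps Per-trial DP values.
#' @param values Per-trial connectivity (or power) values.
#' @param width,step Window width and step in DP units.
#' @param lo,hi DP range covered.
#' @return An object of class `dp_profile`: a data frame with columns
#'   `window_lo`, `window_hi`, `center`, `n`, `mean`, plus an
#'   attribute `members` (list of member value vectors per window).
#' @export
dp_windows <- function(dps, values, width = 0.5, step = 0.1, lo = 1, hi = 4) {
  stopifnot(width > 0, step > 0, hi > lo + width - 1e-12,
            length(dps) == length(values))
  starts <- seq(lo, hi - width + 1e-9, by = step)
  members <- vector("list", length(starts))
  n <- integer(length(starts))
  mu <- rep(NA_real_, length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]; e <- s + width
    inside <- if (abs(e - hi) < 1e-9) {
      dps >= s & dps <= e
    } else {
      dps >= s & dps < e
    }
    vals <- values[inside & !is.na(values)]
    members[[j]] <- vals
    n[j] <- length(vals)
    if (n[j] > 0L) mu[j] <- mean(vals)
  }
  out <- data.frame(window_lo = starts, window_hi = starts + width,
                    center = starts + width / 2, n = n, mean = mu)
  attr(out, "members") <- members
  class(out) <- c("dp_profile", "data.frame")
  out
}

#' Rank-sum tests of every window against the first
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of each window's
#' member values against the first window (DP 1-1.5), the alert-state
#' reference. The first window's own p-value is 1 by convention;
#' windows with fewer than 2 members get a missing p-value.
#'
#' @param profile A `dp_profile` from [dp_windows()].
#' @return The profile with a `raw_p` column added.
#' @export
window_ranksum_vs_first <- function(profile) {
  stopifnot(inherits(profile, "dp_profile"))
  members <- attr(profile, "members")
  ref <- members[[1]]
  if (length(ref) == 0L) stop("first window (DP 1-1.5) is empty")
  p <- rep(NA_real_, nrow(profile))
  p[1] <- 1
  for (j in seq_len(nrow(profile))[-1]) {
    vals <- members[[j]]
    if (length(vals) < 2L) next
    if (stats::sd(c(vals, ref)) == 0) {
      p[j] <- 1  # identical constant samples: no evidence of a shift
    } else {
      p[j] <- suppressWarnings(
        stats::wilcox.test(vals, ref, exact = FALSE)$p.value)
    }
  }
  profile$raw_p <- p
  profile
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; missing entries are passed
#' through untouched and do not count toward the family size.
#'
#' @param pvals Raw p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, order-preserving and capped at 1.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- pvals
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Complete DP-window profile with significance flags
#'
#' Convenience wrapper: windows, rank-sum tests against the first
#' window, FDR adjustment, and the bold-line significance flag
#' (adjusted p below `alpha`, default 0.001).
#'
#' @inheritParams dp_windows
#' @param alpha Display significance level on the adjusted p-values.
#' @return A `dp_profile` with `raw_p`, `adj_p` and `significant`
#'   columns.
#' @export
dp_window_profile <- function(dps, values, width = 0.5, step = 0.1,
                              lo = 1, hi = 4, alpha = 0.001) {
  prof <- window_ranksum_vs_first(dp_windows(dps, values, width, step, lo, hi))
  prof$adj_p <- bh_fdr(prof$raw_p)
  prof$significant <- !is.na(prof$adj_p) & prof$adj_p < alpha
  prof
}

#' Per-subject per-group connectivity means
#'
#' @param values Per-trial (relative) connectivity values.
#' @param groups Per-trial performance groups (factor with levels
#'   optimal, sub_optimal, poor).
#' @param subjects Per-trial subject identifiers.
#' @return Data frame `subject`, `group`, `mean`; only cells with at
#'   least one trial appear.
#' @export
group_summarize <- function(values, groups, subjects) {
  if (length(values) == 0L) stop("empty input")
  stopifnot(length(values) == length(groups),
            length(values) == length(subjects))
  groups <- factor(groups, levels = c("optimal", "sub_optimal", "poor"))
  df <- data.frame(subject = as.character(subjects), group = groups,
                   value = values)
  out <- stats::aggregate(value ~ subject + group, df, mean, drop = TRUE)
  names(out)[3] <- "mean"
  out[order(out$subject, out$group), , drop = FALSE]
}

#' One-way repeated-measures ANOVA over performance groups
#'
#' Within-subject one-way ANOVA of the per-subject per-group means
#' (sphericity assumed): `F = MS_group / MS_error` with degrees of
#' freedom `(k - 1)` and `(k - 1)(n - 1)`. Subjects missing any group
#' are dropped (listwise) with a warning.
#'
#' @param summary_df Output of [group_summarize()].
#' @return List with `F`, `p_value`, `df1`, `df2`, `n_subjects`.
#' @details Degenerate data (zero error mean square, e.g. identical
#'   values everywhere) yields `p = 1` with a warning rather than an
#'   undefined ratio.
#' @export
rm_anova <- function(summary_df) {
  stopifnot(all(c("subject", "group", "mean") %in% names(summary_df)))
  k <- 3L
  complete <- names(which(table(summary_df$subject) == k))
  dropped <- setdiff(unique(summary_df$subject), complete)
  if (length(dropped)) {
    warning("subject(s) without all three groups dropped from ANOVA: ",
            paste(dropped, collapse = ", "))
  }
  df <- summary_df[summary_df$subject %in% complete, ]
  n <- length(complete)
  if (n < 2L) stop("repeated-measures ANOVA needs >= 2 subjects with all three groups")
  y <- df$mean
  grand <- mean(y)
  mg <- tapply(y, df$group, mean)
  ms <- tapply(y, df$subject, mean)
  ss_group <- n * sum((mg - grand)^2)
  ss_subj <- k * sum((ms - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_group <- ss_group / df1
  ms_err <- ss_err / df2
  if (ms_err <= .Machine$double.eps * max(1, abs(ss_tot))) {
    warning("zero error mean square; reporting p = 1")
    return(list(F = NA_real_, p_value = 1, df1 = df1, df2 = df2,
                n_subjects = n))
  }
  Fstat <- ms_group / ms_err
  list(F = Fstat, p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, n_subjects = n)
}

#' Pairwise signed-rank tests between performance groups
#'
#' Two-sided Wilcoxon signed-rank tests on paired per-subject means
#' for the three contrasts optimal vs sub-optimal, sub-optimal vs
#' poor, and optimal vs poor, with Benjamini-Hochberg adjustment
#' across the three comparisons. Subjects lacking either cell of a
#' contrast are dropped from that contrast only (pairwise deletion).
#'
#' @param summary_df Output of [group_summarize()].
#' @return Data frame with `contrast`, `n_pairs`, `p_value`, `adj_p`.
#' @details All-zero paired differences give `p = 1` by convention.
#' @export
pairwise_signed_rank <- function(summary_df) {
  stopifnot(all(c("subject", "group", "mean") %in% names(summary_df)))
  wide <- stats::reshape(summary_df, idvar = "subject", timevar = "group",
                         direction = "wide")
  contrasts <- list(optimal_vs_sub_optimal = c("optimal", "sub_optimal"),
                    sub_optimal_vs_poor = c("sub_optimal", "poor"),
                    optimal_vs_poor = c("optimal", "poor"))
  res <- lapply(names(contrasts), function(nm) {
    g <- contrasts[[nm]]
    a <- wide[[paste0("mean.", g[1])]]
    b <- wide[[paste0("mean.", g[2])]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2L) {
      return(data.frame(contrast = nm, n_pairs = length(a), p_value = NA_real_))
    }
    p <- if (all(a == b)) 1 else {
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    }
    data.frame(contrast = nm, n_pairs = length(a), p_value = p)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_fdr(out$p_value)
  out
}
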