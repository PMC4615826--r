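#' Normalize reaction times by the fastest-decile mean
#'
#' Divides each reaction time by the mean of the smallest
#' `ceiling(0.1 * N)` reaction times (the subject's fastest decile),
#' then clips the result from below at 1: a normalized RT below 1
#' indicates a fully alert response and is mapped to 1.
#'
#' @param rts Numeric vector of reaction times in seconds, all > 0.
#' @return Numeric vector of normalized reaction times, all >= 1.
#' @details The fastest-decile count uses the ceiling rule so the
#'   denominator set is never empty; ties are broken by ascending trial
#'   index. Fewer than 10 trials triggers a warning (the decile mean is
#'   then a single trial). Normalization is invariant to a common
#'   rescaling of all reaction times.
#' @seealso [dp_transform()], [baseline_trial_indices()]
#' @examples
#' normalize_rts(c(1:10))        # denominator = 1
#' normalize_rts(rep(2.2, 20))   # all 1
#' @export
normalize_rts <- function(rts) {
  if (length(rts) == 0L) stop("'rts' is empty")
  if (anyNA(rts) || any(rts <= 0)) stop("all reaction times must be positive")
  n <- length(rts)
  if (n < 10L) warning("fewer than 10 trials; fastest-decile mean is unstable")
  k <- ceiling(0.1 * n)
  denom <- mean(rts[order(rts)[seq_len(k)]])
  pmax(rts / denom, 1)
}

# logistic transform constants: asymptote coefficients
.dp_a <- function() -(1 + exp(-0.5)) / (1 - exp(-0.5))
.dp_b <- function() (2 + 2 * exp(-0.5)) / (1 - exp(-0.5))

#' Driving-performance index from normalized reaction time
#'
#' Bounded logistic transform of the normalized reaction time used as
#' the per-trial vigilance index:
#' \deqn{DP = -\frac{1+e^{-0.5}}{1-e^{-0.5}} +
#'   \frac{2+2e^{-0.5}}{1-e^{-0.5}} \cdot
#'   \frac{1}{1+e^{-0.5\,\mathrm{nrt}}}.}
#' DP equals 1 at normalized RT 1, grows almost linearly up to
#' normalized RT 2.5 (DP about 2.26), reaches about 3.11 at normalized
#' RT 4, and saturates at about 4.08 as the normalized RT grows
#' without bound, so very long (lapse) reaction times cannot dominate
#' the index.
#'
#' @param nrt Normalized reaction time(s), >= 1 (see [normalize_rts()]).
#' @return DP value(s) in `[1, dp_asymptote())`.
#' @seealso [dp_inverse()], [dp_asymptote()], [assign_group()]
#' @examples
#' dp_transform(c(1, 2.5, 4))
#' @export
dp_transform <- function(nrt) {
  if (anyNA(nrt) || any(nrt < 1)) {
    stop("normalized RT must be >= 1 (clip with normalize_rts() first)")
  }
  .dp_a() + .dp_b() / (1 + exp(-0.5 * nrt))
}

#' Upper asymptote of the driving-performance index
#'
#' Closed-form supremum of [dp_transform()] as the normalized reaction
#' time tends to infinity: the sum of its two constant coefficients,
#' \eqn{(1 + 3e^{-0.5})/(1 - e^{-0.5}) \approx 4.083}.
#'
#' @return A single number, about 4.083.
#' @export
dp_asymptote <- function() .dp_a() + .dp_b()

#' Invert the driving-performance transform
#'
#' @param dp DP value(s) in `[1, dp_asymptote())`.
#' @return The normalized reaction time(s) mapping to `dp`.
#' @export
dp_inverse <- function(dp) {
  if (anyNA(dp) || any(dp < 1) || any(dp >= dp_asymptote())) {
    stop("'dp' must lie in [1, dp_asymptote())")
  }
  -2 * log(.dp_b() / (dp - .dp_a()) - 1)
}

#' Assign performance groups from DP
#'
#' Labels each trial `optimal` (DP < 2), `sub_optimal` (2 <= DP <= 3)
#' or `poor` (DP > 3).
#'
#' @param dp DP value(s), >= 1.
#' @param breaks Two increasing group boundaries; defaults `c(2, 3)`.
#'   Both boundaries belong to the sub-optimal group.
#' @return Factor with levels `optimal`, `sub_optimal`, `poor`.
#' @export
assign_group <- function(dp, breaks = c(2, 3)) {
  if (anyNA(dp) || any(dp < 1)) stop("'dp' must be >= 1")
  stopifnot(length(breaks) == 2L, breaks[1] < breaks[2])
  out <- ifelse(dp < breaks[1], "optimal",
                ifelse(dp <= breaks[2], "sub_optimal", "poor"))
  factor(out, levels = c("optimal", "sub_optimal", "poor"))
}

#' Indices of the best-performance (baseline) trials
#'
#' Returns the indices of the `ceiling(0.1 * N)` trials with the
#' smallest DP (the best tenth percentile of performance), used as the
#' within-subject baseline for relative transfer entropy. Ties are
#' broken by ascending trial index.
#'
#' @param dps Numeric vector of per-trial DP values.
#' @return Integer vector of trial indices.
#' @export
baseline_trial_indices <- function(dps) {
  if (length(dps) == 0L) stop("'dps' is empty")
  if (length(dps) < 10L) warning("fewer than 10 trials; baseline is a single trial")
  k <- ceiling(0.1 * length(dps))
  sort(order(dps)[seq_len(k)])
}

#' Per-trial behavioral table
#'
#' Builds the behavioral data frame for one subject from raw reaction
#' times: normalized RT, DP and performance group.
#'
#' @param rts Reaction times in seconds.
#' @param group_breaks Passed to [assign_group()].
#' @return A data frame with columns `trial_index`, `rt_s`,
#'   `normalized_rt`, `dp`, `group`.
#' @export
trial_behavior <- function(rts, group_breaks = c(2, 3)) {
  nrt <- normalize_rts(rts)
  dp <- dp_transform(nrt)
  data.frame(trial_index = seq_along(rts), rt_s = rts, normalized_rt = nrt,
             dp = dp, group = assign_group(dp, group_breaks))
}

#' Write / read a behavioral table as CSV
#'
#' @param behavior Data frame as returned by [trial_behavior()].
#' @param path File path.
#' @return `read_behavior` returns the behavioral data frame with
#'   `group` restored as a factor.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "rt_s", "normalized_rt", "dp", "group")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("behavior file missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(out$rt_s)) {
    stop("missing reaction time for trial(s): ",
         paste(out$trial_index[is.na(out$rt_s)], collapse = ", "))
  }
  out$group <- factor(out$group, levels = c("optimal", "sub_optimal", "poor"))
  out
}
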