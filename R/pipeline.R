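#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults
#' matching the study conditions: six channels (Fz, Cz, C3, C4, Pz,
#' Oz), 1-50 Hz zero-phase FIR band-pass, decimation to 250 Hz, 1-s
#' baseline epochs, Kraskov estimator with k = 4 and Theiler window 1,
#' prediction-time candidates 5-100 ms, DP windows of width 0.5
#' stepped by 0.1 over DP 1-4, group boundaries at DP 2 and 3,
#' profile significance at FDR-adjusted p < 0.001 and group tests at
#' 0.05 / 0.01.
#'
#' @param channels Channel labels analyzed.
#' @param filter A [filter_spec()].
#' @param fs_target Analysis sampling rate in Hz.
#' @param epoch_len Baseline epoch length in seconds.
#' @param embedding An [embedding_spec()] used for every pair, or the
#'   string `"auto"` to resolve delay and dimensions per subject and
#'   pair from the data (autocorrelation decay and Cao's criterion on
#'   the pooled baseline samples).
#' @param u_candidates_ms Prediction-time candidates in ms (used when
#'   `select_u = TRUE`).
#' @param select_u Scan the prediction-time candidates per subject and
#'   pair instead of using `embedding$u` (default `FALSE`).
#' @param window_width,window_step,dp_lo,dp_hi DP moving-window layout.
#' @param group_breaks Performance-group boundaries (DP units).
#' @param alpha_profile Bold-line significance level on FDR-adjusted
#'   window p-values.
#' @param alpha_group Significance level for the group contrasts.
#' @param log_power Correlate log10 band power (rather than linear
#'   power) with DP.
#' @param fdr_family `"per_pair"` (adjust across the 26 windows within
#'   each ordered pair) or `"global"` (across all pairs jointly).
#' @param compute_gc Also compute per-trial Granger causality.
#' @param gc_order Fixed VAR order, or `NULL` to select by BIC per
#'   subject and pair.
#' @param gc_p_max Largest BIC candidate order.
#' @param time_shift_screen Run the instantaneous-mixing screen per
#'   subject and pair.
#' @param seed Run seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(channels = c("Fz", "Cz", "C3", "C4", "Pz", "Oz"),
                            filter = filter_spec(1, 50),
                            fs_target = 250,
                            epoch_len = 1,
                            embedding = embedding_spec(d = 2, m = 2, tau = 1,
                                                       u = 1, k = 4,
                                                       theiler = 1),
                            u_candidates_ms = c(5, 10, 20, 40, 60, 80, 100),
                            select_u = FALSE,
                            window_width = 0.5, window_step = 0.1,
                            dp_lo = 1, dp_hi = 4,
                            group_breaks = c(2, 3),
                            alpha_profile = 0.001,
                            alpha_group = 0.05,
                            log_power = TRUE,
                            fdr_family = c("per_pair", "global"),
                            compute_gc = TRUE,
                            gc_order = NULL, gc_p_max = 8L,
                            time_shift_screen = FALSE,
                            seed = 1L) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(filter, "filter_spec"),
            identical(embedding, "auto") || inherits(embedding, "embedding_spec"),
            length(u_candidates_ms) >= 1L, window_width > 0, window_step > 0,
            dp_hi > dp_lo, length(group_breaks) == 2L)
  structure(list(channels = channels, filter = filter,
                 fs_target = fs_target, epoch_len = epoch_len,
                 embedding = embedding, u_candidates_ms = u_candidates_ms,
                 select_u = select_u, window_width = window_width,
                 window_step = window_step, dp_lo = dp_lo, dp_hi = dp_hi,
                 group_breaks = group_breaks, alpha_profile = alpha_profile,
                 alpha_group = alpha_group, log_power = log_power,
                 fdr_family = fdr_family, compute_gc = compute_gc,
                 gc_order = gc_order, gc_p_max = as.integer(gc_p_max),
                 time_shift_screen = time_shift_screen,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.all_ordered_pairs <- function(channels) {
  out <- list()
  for (a in channels) for (b in channels) if (a != b) out[[length(out) + 1L]] <- c(a, b)
  out
}

.normalize_pairs <- function(pairs, channels) {
  if (is.null(pairs)) return(.all_ordered_pairs(channels))
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  for (p in pairs) {
    if (length(p) != 2L || p[1] == p[2]) stop("each pair must be two distinct channel labels")
    miss <- setdiff(p, channels)
    if (length(miss)) stop("unknown channel label(s): ", paste(miss, collapse = ", "))
  }
  pairs
}

# resolve the embedding for one subject/pair on pooled baseline epochs
.resolve_embedding <- function(src_m, snk_m, config) {
  if (!identical(config$embedding, "auto")) return(config$embedding)
  pooled_src <- as.numeric(t(src_m))
  pooled_snk <- as.numeric(t(snk_m))
  tau <- max(select_delay(pooled_snk), 1L)
  d <- cao_dimension(pooled_snk, tau, d_max = 6L)
  m <- cao_dimension(pooled_src, tau, d_max = 6L)
  embedding_spec(d = d, m = m, tau = tau, u = 1L, k = 4L, theiler = 1L)
}

#' DP-sorted effective-connectivity analysis
#'
#' End-to-end analysis of one or more sessions: zero-phase band-pass
#' and decimation, 1-s baseline epoch extraction, behavioral DP per
#' trial, per-trial directed transfer entropy (and optionally Granger
#' causality) for the requested channel pairs, within-subject baseline
#' normalization, pooled DP moving-window profiles with rank-sum tests
#' and FDR adjustment, performance-group contrasts (repeated-measures
#' ANOVA plus pairwise signed-rank tests), and band-power/DP
#' correlations.
#'
#' @param sessions One `eeg_session` or a list of them (one per
#'   subject), e.g. from [gen_session()] / [simulate_study()] or
#'   [read_session()].
#' @param pairs Ordered channel pairs to analyze: list of
#'   `c(source, sink)` (or a two-column matrix). `NULL` analyzes all
#'   30 ordered pairs of the configured channels.
#' @param config A [pipeline_config()].
#' @return An object of class `dpconn` with elements `trials`
#'   (behavior per subject and trial), `connectivity` (long per-trial
#'   table with `te_bits`, `te_rel` and optionally `gc`, `gc_rel`),
#'   `profiles` (per pair: `dp_profile` of relative TE, and of GC),
#'   `group_tests` (per pair: ANOVA and pairwise signed-rank),
#'   `band_correlations`, `time_shift` (screen results, if enabled),
#'   `embeddings` (resolved spec per subject and pair), `pairs`,
#'   `config`.
#' @seealso [plot.dpconn()], [summary.dpconn()]
#' @export
dp_connectivity <- function(sessions, pairs = NULL,
                            config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(sessions, "eeg_session")) sessions <- list(sessions)
  pairs <- .normalize_pairs(pairs, config$channels)
  pair_id <- vapply(pairs, function(p) paste(p, collapse = "->"), "")

  trials_l <- list(); conn_l <- list(); power_l <- list()
  shift_l <- list(); emb_l <- list()
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    stopifnot(inherits(ses, "eeg_session"))
    miss <- setdiff(config$channels, ses$channels)
    if (length(miss)) stop("session ", s, " lacks channel(s): ",
                           paste(miss, collapse = ", "))
    pre <- preprocess_session(ses, config$filter, config$fs_target)
    ep <- extract_baseline_epochs(pre, config$epoch_len)
    kept <- attr(ep, "trial_index")
    beh <- trial_behavior(ses$rt_s, config$group_breaks)[kept, ]
    subj <- sprintf("S%02d", s)
    trials_l[[s]] <- cbind(subject = subj, beh)

    pw <- band_power_table(ep)
    pw$subject <- subj
    pw$dp <- beh$dp[pw$trial]
    power_l[[s]] <- pw

    base_idx <- baseline_trial_indices(beh$dp)
    for (pi in seq_along(pairs)) {
      src_m <- channel_epochs(ep, pairs[[pi]][1])
      snk_m <- channel_epochs(ep, pairs[[pi]][2])
      spec <- .resolve_embedding(src_m, snk_m, config)
      if (config$select_u) {
        pooled_idx <- seq_len(min(20L, nrow(src_m)))
        sel <- select_u(src_m[pooled_idx, , drop = FALSE],
                        snk_m[pooled_idx, , drop = FALSE], spec,
                        config$u_candidates_ms, config$fs_target)
        spec$u <- sel$u
      }
      emb_l[[paste(subj, pair_id[pi])]] <-
        data.frame(subject = subj, pair = pair_id[pi], d = spec$d, m = spec$m,
                   tau = spec$tau, u = spec$u, k = spec$k,
                   theiler = spec$theiler)
      if (config$time_shift_screen) {
        ts <- time_shift_test(src_m, snk_m, spec,
                              seed = derive_seed(config$seed,
                                                 paste0("shift", s, pair_id[pi])))
        shift_l[[paste(subj, pair_id[pi])]] <-
          data.frame(subject = subj, pair = pair_id[pi], pass = ts$pass,
                     p_value = ts$p_value, mean_diff = ts$mean_diff)
      }
      nt <- nrow(src_m)
      te <- vapply(seq_len(nt), function(i) {
        ksg_te(src_m[i, ], snk_m[i, ], spec)$te_bits
      }, numeric(1))
      rec <- data.frame(subject = subj, trial = beh$trial_index,
                        source = pairs[[pi]][1], sink = pairs[[pi]][2],
                        dp = beh$dp, group = beh$group,
                        te_bits = te, te_rel = relative_te(te, base_idx))
      if (config$compute_gc) {
        ord <- config$gc_order
        if (is.null(ord)) {
          ord <- fit_var_order_bic(as.numeric(t(src_m[seq_len(min(4L, nt)), ,
                                                      drop = FALSE])),
                                   as.numeric(t(snk_m[seq_len(min(4L, nt)), ,
                                                      drop = FALSE])),
                                   config$gc_p_max)
        }
        gc <- vapply(seq_len(nt), function(i) {
          granger(snk_m[i, ], src_m[i, ], ord)
        }, numeric(1))
        rec$gc <- gc
        rec$gc_rel <- relative_te(gc, base_idx)
        rec$gc_order <- ord
      }
      conn_l[[paste(subj, pair_id[pi])]] <- rec
    }
  }
  trials <- do.call(rbind, trials_l)
  conn <- do.call(rbind, conn_l)
  rownames(conn) <- NULL
  power <- do.call(rbind, power_l)

  # pooled DP-window profiles per pair
  profiles <- list()
  for (pi in seq_along(pairs)) {
    sel <- conn$source == pairs[[pi]][1] & conn$sink == pairs[[pi]][2]
    te_prof <- window_ranksum_vs_first(
      dp_windows(conn$dp[sel], conn$te_rel[sel], config$window_width,
                 config$window_step, config$dp_lo, config$dp_hi))
    gc_prof <- if (config$compute_gc) {
      window_ranksum_vs_first(
        dp_windows(conn$dp[sel], conn$gc_rel[sel], config$window_width,
                   config$window_step, config$dp_lo, config$dp_hi))
    }
    profiles[[pair_id[pi]]] <- list(te = te_prof, gc = gc_prof)
  }
  # FDR family: within each pair, or across all pairs jointly
  if (config$fdr_family == "per_pair") {
    for (id in names(profiles)) {
      for (meas in c("te", "gc")) {
        pr <- profiles[[id]][[meas]]
        if (is.null(pr)) next
        pr$adj_p <- bh_fdr(pr$raw_p)
        pr$significant <- !is.na(pr$adj_p) & pr$adj_p < config$alpha_profile
        profiles[[id]][[meas]] <- pr
      }
    }
  } else {
    for (meas in c("te", "gc")) {
      if (meas == "gc" && !config$compute_gc) next
      all_p <- unlist(lapply(profiles, function(pp) pp[[meas]]$raw_p))
      adj <- bh_fdr(all_p)
      off <- 0L
      for (id in names(profiles)) {
        pr <- profiles[[id]][[meas]]
        pr$adj_p <- adj[off + seq_len(nrow(pr))]
        pr$significant <- !is.na(pr$adj_p) & pr$adj_p < config$alpha_profile
        profiles[[id]][[meas]] <- pr
        off <- off + nrow(pr)
      }
    }
  }

  # group analysis per pair on relative TE
  group_tests <- list()
  for (pi in seq_along(pairs)) {
    sel <- conn$source == pairs[[pi]][1] & conn$sink == pairs[[pi]][2]
    gs <- group_summarize(conn$te_rel[sel], conn$group[sel], conn$subject[sel])
    anova <- tryCatch(suppressWarnings(rm_anova(gs)), error = function(e) NULL)
    pw <- tryCatch(pairwise_signed_rank(gs), error = function(e) NULL)
    group_tests[[pair_id[pi]]] <- list(summary = gs, anova = anova,
                                       pairwise = pw)
  }

  # band-power/DP correlations pooled over subjects
  power$value <- if (config$log_power) log10(power$power) else power$power
  bc <- unique(power[, c("channel", "band")])
  rownames(bc) <- NULL
  bc$r <- vapply(seq_len(nrow(bc)), function(i) {
    sel <- power$channel == bc$channel[i] & power$band == bc$band[i]
    band_dp_correlation(power$value[sel], power$dp[sel])
  }, numeric(1))

  structure(list(trials = trials, connectivity = conn, profiles = profiles,
                 group_tests = group_tests, band_correlations = bc,
                 band_power = power,
                 time_shift = if (length(shift_l)) do.call(rbind, shift_l),
                 embeddings = do.call(rbind, emb_l),
                 pairs = pairs, pair_id = pair_id, config = config,
                 n_subjects = length(sessions)),
            class = "dpconn")
}

#' @export
print.dpconn <- function(x, ...) {
  cat(sprintf("DP-sorted connectivity analysis: %d subject(s), %d trial(s), %d pair(s)\n",
              x$n_subjects, nrow(x$trials), length(x$pairs)))
  cat(sprintf("  DP windows: width %.2f step %.2f over [%g, %g]; FDR family: %s\n",
              x$config$window_width, x$config$window_step, x$config$dp_lo,
              x$config$dp_hi, x$config$fdr_family))
  for (id in x$pair_id) {
    pr <- x$profiles[[id]]$te
    pk <- pr$center[which.max(pr$mean)]
    cat(sprintf("  %-10s peak relative TE at DP %.2f; %d/%d windows significant\n",
                id, pk, sum(pr$significant, na.rm = TRUE), nrow(pr)))
  }
  invisible(x)
}

#' Summarize a DP-connectivity analysis
#'
#' @param object A `dpconn` object.
#' @param ... Unused.
#' @return A data frame with one row per pair: profile peak location,
#'   number of significant windows, ANOVA F and p, and the three
#'   pairwise adjusted p-values.
#' @export
summary.dpconn <- function(object, ...) {
  rows <- lapply(object$pair_id, function(id) {
    pr <- object$profiles[[id]]$te
    gt <- object$group_tests[[id]]
    pk <- pr$center[which.max(pr$mean)]
    getp <- function(nm) {
      if (is.null(gt$pairwise)) return(NA_real_)
      gt$pairwise$adj_p[gt$pairwise$contrast == nm]
    }
    data.frame(pair = id, peak_center = pk,
               n_sig_windows = sum(pr$significant, na.rm = TRUE),
               anova_F = if (is.null(gt$anova)) NA_real_ else gt$anova$F,
               anova_p = if (is.null(gt$anova)) NA_real_ else gt$anova$p_value,
               p_opt_vs_sub = getp("optimal_vs_sub_optimal"),
               p_sub_vs_poor = getp("sub_optimal_vs_poor"),
               p_opt_vs_poor = getp("optimal_vs_poor"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a DP-window connectivity profile
#'
#' Draws the pooled mean relative connectivity against the DP window
#' centers for one ordered pair; segments whose FDR-adjusted p-value
#' is below the configured display level are drawn bold, and the
#' Granger-causality profile can be overlaid for comparison.
#'
#' @param x A `dpconn` object.
#' @param pair Pair id, e.g. `"Cz->Pz"` (default the first analyzed
#'   pair).
#' @param show_gc Overlay the GC profile if available.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dpconn <- function(x, pair = x$pair_id[1], show_gc = TRUE, ...) {
  pr <- x$profiles[[pair]]$te
  if (is.null(pr)) stop("unknown pair: ", pair)
  gc <- x$profiles[[pair]]$gc
  ylim <- range(c(pr$mean, if (!is.null(gc)) gc$mean), na.rm = TRUE)
  graphics::plot(pr$center, pr$mean, type = "l", col = "red", lwd = 1,
                 xlab = "driving performance (window center)",
                 ylab = "relative connectivity (bits / nats)",
                 main = paste0("DP-sorted connectivity: ", pair),
                 ylim = ylim, ...)
  sig <- which(pr$significant)
  if (length(sig)) {
    graphics::lines(pr$center[sig], pr$mean[sig], col = "red", lwd = 3,
                    type = "p", pch = 16, cex = 0.7)
  }
  if (show_gc && !is.null(gc)) {
    graphics::lines(gc$center, gc$mean, col = "blue", lwd = 1)
    graphics::legend("topleft", legend = c("transfer entropy", "Granger causality"),
                     col = c("red", "blue"), lwd = 2, bty = "n")
  }
  invisible(x)
}
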