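#' Write / read a session to disk
#'
#' Sessions are stored as a directory holding a flat binary array of
#' doubles (`signal.bin`, channels-by-samples in column-major order)
#' plus a JSON sidecar (`session.json`) with the sampling rate,
#' channel labels, trial onsets, reaction times, seed and the
#' ground-truth coupling specification. The round trip is lossless.
#'
#' @param session An `eeg_session`.
#' @param path Directory to create/overwrite.
#' @return `write_session` returns `path` invisibly; `read_session`
#'   returns the reconstructed `eeg_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "signal.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(session$data), con, size = 8, endian = "little")
  truths <- lapply(session$truths, function(tr) {
    tr[c("source", "sink", "lag", "shape", "strength", "peak_dp", "width",
         "floor_frac")]
  })
  meta <- list(schema_version = 1L,
               fs = session$fs,
               channels = session$channels,
               n_samples = ncol(session$data),
               onset_sample = session$onset_sample,
               rt_s = session$rt_s,
               vigilance = session$vigilance,
               seed = session$seed,
               truths = truths)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "session.json")
  bin_path <- file.path(path, "signal.bin")
  if (!file.exists(meta_path) || !file.exists(bin_path)) {
    stop("not a session directory: ", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L) {
    stop("unsupported session schema version")
  }
  nch <- length(meta$channels)
  expected <- nch * meta$n_samples
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = expected + 1L, size = 8,
                  endian = "little")
  if (length(vals) != expected) {
    stop("array/sidecar shape disagreement: expected ", expected,
         " samples, found ", length(vals))
  }
  if (length(meta$rt_s) != length(meta$onset_sample)) {
    stop("sidecar lists ", length(meta$onset_sample), " onsets but ",
         length(meta$rt_s), " reaction times")
  }
  truths <- list()
  if (length(meta$truths)) {
    tdf <- meta$truths
    truths <- lapply(seq_len(nrow(tdf)), function(i) {
      coupling_truth(tdf$source[i], tdf$sink[i], tdf$lag[i], tdf$shape[i],
                     tdf$strength[i], tdf$peak_dp[i], tdf$width[i],
                     tdf$floor_frac[i])
    })
  }
  data <- matrix(vals, nrow = nch)
  rownames(data) <- meta$channels
  structure(list(data = data, fs = meta$fs, channels = meta$channels,
                 onset_sample = as.integer(meta$onset_sample),
                 onset_s = (meta$onset_sample - 1) / meta$fs,
                 rt_s = meta$rt_s, vigilance = meta$vigilance,
                 weights = NULL, coupling = NULL, truths = truths,
                 config = NULL, seed = meta$seed),
            class = "eeg_session")
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Executes simulate/ingest, preprocessing, behavior, connectivity,
#' spectra and statistics end to end and writes tidy CSV artifacts
#' plus a JSON run manifest (configuration, seed, package version) to
#' `out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param input `"simulate"` or a path readable by [read_session()]
#'   (or a list of such paths, one per subject).
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param pairs Ordered channel pairs (see [dp_connectivity()]).
#' @param n_subjects,n_trials,truths Simulation parameters (used when
#'   `input = "simulate"`).
#' @return The fitted `dpconn` object, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), input = "simulate",
                         out_dir = NULL, pairs = NULL, n_subjects = 1L,
                         n_trials = 40L, truths = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sessions <- stage("ingest", {
    if (identical(input, "simulate")) {
      lapply(simulate_study(n_subjects, n_trials, truths,
                            seed = derive_seed(config$seed, "simulate"),
                            channels = config$channels),
             `[[`, "session")
    } else {
      lapply(as.list(input), read_session)
    }
  })
  fit <- stage("analysis", dp_connectivity(sessions, pairs, config))
  if (!is.null(out_dir)) {
    stage("export", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(fit$trials, file.path(out_dir, "behavior.csv"),
                       row.names = FALSE)
      utils::write.csv(fit$connectivity,
                       file.path(out_dir, "connectivity.csv"),
                       row.names = FALSE)
      prof <- do.call(rbind, lapply(names(fit$profiles), function(id) {
        pr <- fit$profiles[[id]]$te
        cbind(pair = id, as.data.frame(pr))
      }))
      utils::write.csv(prof, file.path(out_dir, "profiles.csv"),
                       row.names = FALSE)
      utils::write.csv(summary(fit), file.path(out_dir, "group_tests.csv"),
                       row.names = FALSE)
      utils::write.csv(fit$band_correlations,
                       file.path(out_dir, "band_correlations.csv"),
                       row.names = FALSE)
      manifest <- list(
        package_version = as.character(utils::packageVersion("drowsyTE")),
        seed = config$seed,
        n_subjects = fit$n_subjects,
        pairs = fit$pair_id,
        config = config[setdiff(names(config),
                                c("filter", "embedding"))],
        filter = unclass(config$filter),
        embedding = if (identical(config$embedding, "auto")) "auto"
                    else unclass(config$embedding))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }
  invisible(fit)
}
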