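# S3 containers: multichannel recordings, trial tables, spike trains.

#' Multichannel voltage recording
#'
#' A thin container for a channels x samples voltage matrix plus its sampling
#' rate and spatial scale. All analysis functions in the package accept and
#' return this class. Sample indices are 1-based throughout the package;
#' exported tables use seconds.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param scale recording scale, `"iEEG"` (macro) or `"LFP"` (micro).
#' @param channel_names optional character vector of channel labels.
#' @return an object of class `ts_recording`.
#' @export
ts_recording <- function(data, fs, scale = c("iEEG", "LFP"),
                         channel_names = NULL) {
  scale <- match.arg(scale)
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) stop("data must be a numeric matrix")
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  if (is.null(channel_names)) {
    channel_names <- paste0(tolower(scale), seq_len(nrow(data)))
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, scale = scale),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$scale, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param ts a `ts_recording`.
#' @return integer count.
#' @export
n_channels <- function(ts) nrow(ts$data)

#' @rdname n_channels
#' @export
n_samples <- function(ts) ncol(ts$data)

#' Trial table
#'
#' Per-trial epoch boundaries on the session clock, the alignment sample
#' (e.g. vocalization onset during retrieval) and the behavioural outcome.
#'
#' @param start_sample,end_sample integer vectors; trials are half-open
#'   `[start, end)` in 1-based samples.
#' @param align_sample integer vector, alignment time per trial.
#' @param label character vector: `"correct"`, `"incorrect"` or `"pass"`.
#' @return a `data.frame` with class `trial_table`.
#' @export
trial_table <- function(start_sample, end_sample, align_sample = NULL,
                        label = NULL) {
  n <- length(start_sample)
  if (is.null(align_sample)) align_sample <- end_sample
  if (is.null(label)) label <- rep("correct", n)
  if (any(end_sample <= start_sample)) stop("trials must have positive length")
  out <- data.frame(trial = seq_len(n),
                    start_sample = as.integer(start_sample),
                    end_sample = as.integer(end_sample),
                    align_sample = as.integer(align_sample),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Spike train of a single unit
#'
#' @param unit unit identifier.
#' @param samples strictly increasing 1-based spike sample indices.
#' @param fs sampling rate in Hz.
#' @param channel recording channel the unit was isolated on.
#' @param waveforms optional numeric matrix of per-spike waveforms
#'   (spikes x 32 samples).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(unit, samples, fs, channel = NA, waveforms = NULL) {
  samples <- as.integer(samples)
  if (is.unsorted(samples, strictly = TRUE))
    stop("spike samples must be strictly increasing")
  if (length(samples) && samples[1L] < 1L) stop("spike samples must be >= 1")
  if (!is.null(waveforms)) {
    waveforms <- as.matrix(waveforms)
    if (nrow(waveforms) != length(samples))
      stop("one waveform per spike required")
  }
  structure(list(unit = unit, samples = samples, fs = fs, channel = channel,
                 waveforms = waveforms),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes @ %g Hz%s\n", x$unit,
              length(x$samples), x$fs,
              if (is.null(x$waveforms)) "" else " (+waveforms)"))
  invisible(x)
}

#' Export ripple/event tables as TSV
#'
#' Writes detected events in a plain-text layout with times in seconds:
#' channel, start_s, end_s, duration_ms, peak_z, peak_s, band_lo, band_hi.
#'
#' @param events a `ripple_events` data.frame from [detect_ripples()].
#' @param file output path.
#' @param fs sampling rate used to convert samples to seconds.
#' @return the written data.frame, invisibly.
#' @export
write_events_tsv <- function(events, file, fs) {
  out <- data.frame(channel = events$channel,
                    start_s = (events$start_sample - 1L) / fs,
                    end_s = (events$end_sample - 1L) / fs,
                    duration_ms = events$duration_ms,
                    peak_z = events$peak_z,
                    peak_s = (events$peak_sample - 1L) / fs,
                    band_lo = events$band_lo,
                    band_hi = events$band_hi)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Export an artifact mask as a BED-like TSV
#'
#' One row per flagged run: channel, start_sample, end_sample, reason.
#'
#' @param mask an `artifact_mask` from [mask_transient_artifacts()].
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
write_mask_tsv <- function(mask, file) {
  rows <- list()
  for (ch in seq_len(nrow(mask$mask))) {
    runs <- logical_runs(mask$mask[ch, ])
    if (nrow(runs) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      channel = rownames(mask$mask)[ch] %||% ch,
      start_sample = runs[, "start"], end_sample = runs[, "end"],
      reason = mask$reason[ch])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(), start_sample = integer(),
               end_sample = integer(), reason = character())
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Export a synthetic session in plain-text form
#'
#' Writes the event, trial, spike and ground-truth tables of a session built
#' by [build_session()] as TSV files under `dir` (voltage matrices are not
#' written; regenerate them from the stored config and seed).
#'
#' @param session a `ripple_session`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_session_tsv <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- session$lfp$fs
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(session$trials, "trials.tsv")
  w(session$truth$ripples, "truth_ripples.tsv")
  spk <- do.call(rbind, lapply(session$spikes, function(s)
    data.frame(unit = s$unit, time_s = (s$samples - 1L) / fs)))
  w(spk %||% data.frame(unit = character(), time_s = numeric()), "spikes.tsv")
  if (length(session$truth$ied_samples))
    w(data.frame(ied_s = (session$truth$ied_samples - 1L) / fs), "truth_ied.tsv")
  invisible(paths)
}
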