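# Ripple event detection: Hilbert-envelope thresholding with strict and
# relaxed presets, raster/rate summaries, a 1/f-referenced narrowband episode
# detector, and the detection-parameter sweep.

#' Ripple detection parameters
#'
#' The strict preset requires the ripple-band envelope to exceed 2 SD (event
#' extent), last at least 25 ms, and reach a maximum above 3 SD; adjacent
#' events separated by less than 15 ms are joined. The relaxed preset —
#' used to expose the continuum of sub-threshold events — lowers the extent
#' threshold to 1 SD, the maximum to 2 SD and the minimum duration to 10 ms.
#' No upper duration limit is applied.
#'
#' @param band detection band, Hz (80-120 by default; use 120-200 as a
#'   higher-frequency control).
#' @param envelope_threshold extent threshold in envelope SD.
#' @param max_threshold maximum-amplitude threshold in envelope SD.
#' @param min_duration_ms minimum event duration, ms.
#' @param join_gap_ms events closer than this are merged, ms.
#' @param preset `"strict"` or `"relaxed"`; fills the defaults above.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(band = c(80, 120),
                             envelope_threshold = NULL,
                             max_threshold = NULL,
                             min_duration_ms = NULL,
                             join_gap_ms = 15,
                             preset = c("strict", "relaxed")) {
  preset <- match.arg(preset)
  def <- if (preset == "strict") c(2, 3, 25) else c(1, 2, 10)
  p <- list(band = band,
            envelope_threshold = envelope_threshold %||% def[1],
            max_threshold = max_threshold %||% def[2],
            min_duration_ms = min_duration_ms %||% def[3],
            join_gap_ms = join_gap_ms,
            preset = preset)
  if (p$max_threshold < p$envelope_threshold)
    stop("max_threshold must be >= envelope_threshold")
  if (p$min_duration_ms <= 0) stop("min_duration_ms must be positive")
  structure(p, class = "detection_params")
}

#' Detect ripple events by Hilbert-envelope thresholding
#'
#' Band-passes each channel (zero-phase second-order Butterworth design),
#' extracts the Hilbert envelope, and z-scores it against the envelope mean
#' and SD of the whole session computed per channel with masked samples
#' excluded. Candidate intervals where the envelope exceeds the extent
#' threshold are merged when separated by less than the join gap, then kept
#' if they last at least the minimum duration *and* peak above the
#' maximum-amplitude threshold. Events overlapping any masked sample
#' (interictal discharges, movement artifacts) are discarded.
#'
#' Event start/end are the extent-threshold crossing samples (half-open
#' `[start, end)`); the 2 SD criterion defines the event extent and the 3 SD
#' criterion validates it.
#'
#' @param ts a preprocessed [ts_recording()].
#' @param params a [detection_params()].
#' @param mask optional `artifact_mask` (or logical matrix) of the same
#'   dimensions as the recording.
#' @param envelope_stats `"session"` (default) or `"trials"`; with
#'   `"trials"` supply `trials` and the envelope mean/SD are computed over
#'   trial samples only.
#' @param trials optional [trial_table()] for `envelope_stats = "trials"`.
#' @return `ripple_events` data.frame: channel, start_sample, end_sample,
#'   peak_sample, peak_z, duration_ms, band_lo, band_hi.
#' @export
detect_ripples <- function(ts, params = detection_params(), mask = NULL,
                           envelope_stats = c("session", "trials"),
                           trials = NULL) {
  envelope_stats <- match.arg(envelope_stats)
  fs <- ts$fs
  n <- n_samples(ts)
  maskm <- if (inherits(mask, "artifact_mask")) mask$mask else mask
  if (!is.null(maskm) && (!is.matrix(maskm) || any(dim(maskm) != dim(ts$data))))
    stop("mask must match the recording dimensions")
  min_len <- ceiling(params$min_duration_ms / 1000 * fs)
  gap_len <- params$join_gap_ms / 1000 * fs
  stat_keep <- rep(TRUE, n)
  if (envelope_stats == "trials") {
    if (is.null(trials)) stop("trials required for envelope_stats = 'trials'")
    stat_keep <- rep(FALSE, n)
    for (i in seq_len(nrow(trials)))
      stat_keep[trials$start_sample[i]:(trials$end_sample[i] - 1L)] <- TRUE
  }
  out <- list()
  for (ch in seq_len(n_channels(ts))) {
    env <- Mod(analytic_signal(
      signal::filtfilt(.design_bandpass(fs, params$band, 2), ts$data[ch, ])))
    chmask <- if (is.null(maskm)) rep(FALSE, n) else maskm[ch, ]
    keep <- stat_keep & !chmask
    if (!any(keep)) {
      warning(sprintf("channel %d fully masked; no events", ch))
      next
    }
    z <- (env - mean(env[keep])) / stats::sd(env[keep])
    runs <- logical_runs(z > params$envelope_threshold)
    if (nrow(runs) == 0L) next
    # join adjacent candidates separated by < join_gap (end-to-start, strict)
    if (nrow(runs) > 1L) {
      gaps <- runs[-1L, "start"] - runs[-nrow(runs), "end"] - 1L
      grp <- cumsum(c(0L, as.integer(!(gaps < gap_len))))
      pieces <- split(seq_len(nrow(runs)), grp)
      runs <- cbind(
        start = vapply(pieces, function(i) runs[i[1L], "start"], numeric(1)),
        end = vapply(pieces, function(i) runs[i[length(i)], "end"], numeric(1)))
    }
    dur_ok <- (runs[, "end"] - runs[, "start"] + 1L) >= min_len
    runs <- runs[dur_ok, , drop = FALSE]
    if (nrow(runs) == 0L) next
    peak_idx <- vapply(seq_len(nrow(runs)), function(i) {
      span <- runs[i, "start"]:runs[i, "end"]
      span[which.max(z[span])]
    }, numeric(1))
    peak_z <- z[peak_idx]
    sel <- peak_z > params$max_threshold
    if (any(chmask) && any(sel)) {
      masked_runs <- logical_runs(chmask)
      if (nrow(masked_runs)) {
        ovl <- intervals_overlap(runs[, "start"], runs[, "end"],
                                 masked_runs[, "start"], masked_runs[, "end"])
        sel <- sel & !apply(ovl, 1L, any)
      }
    }
    if (!any(sel)) next
    runs <- runs[sel, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      channel = ch,
      start_sample = runs[, "start"],
      end_sample = runs[, "end"] + 1L,           # half-open
      peak_sample = as.integer(peak_idx[sel]),
      peak_z = peak_z[sel],
      duration_ms = (runs[, "end"] - runs[, "start"] + 1L) / fs * 1000,
      band_lo = params$band[1], band_hi = params$band[2])
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(channel = integer(), start_sample = integer(),
               end_sample = integer(), peak_sample = integer(),
               peak_z = numeric(), duration_ms = numeric(),
               band_lo = numeric(), band_hi = numeric())
  rownames(ev) <- NULL
  class(ev) <- c("ripple_events", "data.frame")
  ev
}

#' Per-trial ripple raster and rate
#'
#' Aligns event peak times to the per-trial alignment point, builds a raster
#' of relative times, and estimates a smoothed rate time series per trial
#' (Gaussian kernel). Also returns the session-mean event rate over trial
#' time.
#'
#' @param events a `ripple_events` data.frame.
#' @param trials a [trial_table()] on the same session clock.
#' @param fs sampling rate, Hz.
#' @param kernel_sd_ms rate smoothing kernel SD, ms.
#' @param channel optional channel restriction.
#' @return list: `raster` (per-trial relative peak times, s), `time_s` (rate
#'   grid relative to alignment), `rate` (trials x time matrix, Hz),
#'   `mean_rate` (scalar session mean, Hz).
#' @export
ripple_raster_rate <- function(events, trials, fs, kernel_sd_ms = 100,
                               channel = NULL) {
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial table")
  if (!is.null(channel)) events <- events[events$channel %in% channel, , drop = FALSE]
  rel_lo <- min(trials$start_sample - trials$align_sample) / fs
  rel_hi <- max(trials$end_sample - trials$align_sample) / fs
  grid <- seq(rel_lo, rel_hi, by = 1 / fs)
  kern <- gaussian_kernel(kernel_sd_ms / 1000, fs)
  raster <- vector("list", nrow(trials))
  rate <- matrix(0, nrow(trials), length(grid))
  total_events <- 0L
  total_time <- 0
  for (i in seq_len(nrow(trials))) {
    inb <- events$peak_sample >= trials$start_sample[i] &
      events$peak_sample < trials$end_sample[i]
    rel <- (events$peak_sample[inb] - trials$align_sample[i]) / fs
    raster[[i]] <- rel
    total_events <- total_events + sum(inb)
    total_time <- total_time + (trials$end_sample[i] - trials$start_sample[i]) / fs
    if (length(rel)) {
      delta <- numeric(length(grid))
      pos <- pmin(length(grid), pmax(1L, round((rel - rel_lo) * fs) + 1L))
      for (p in pos) delta[p] <- delta[p] + 1
      rate[i, ] <- conv_reflect(delta, kern) * sum(kern)  # spikes/s
    }
  }
  list(raster = raster, time_s = grid, rate = rate,
       mean_rate = total_events / total_time)
}

#' Narrowband oscillation episodes referenced to the 1/f background
#'
#' An independent detector used to corroborate threshold-based ripple
#' detection. Per trial: the mean wavelet power spectrum is fit with a
#' robust line in log-log coordinates over `fit_range`; contiguous
#' frequencies exceeding the fit define narrowband bands; the signal is
#' band-passed within each band and the instantaneous frequency is estimated
#' by frequency sliding (smoothed derivative of the unwrapped Hilbert
#' phase); samples whose band power falls below the 1/f fit are removed, and
#' the remaining runs form episodes.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate, Hz.
#' @param trials optional [trial_table()]; when `NULL` the whole signal is
#'   one trial.
#' @param fit_range frequency range of the 1/f fit, Hz.
#' @param n_freqs wavelet grid resolution within `fit_range`.
#' @param n_cycles wavelet number.
#' @param robust use `MASS::rlm` for the 1/f fit (falls back to `lm` if it
#'   fails to converge)?
#' @param min_cycles episodes shorter than this many cycles of the band
#'   center are dropped.
#' @return data.frame: trial, band_lo, band_hi, start_sample, end_sample
#'   (session clock), duration_ms, center_freq (median instantaneous
#'   frequency).
#' @export
modal_narrowband_episodes <- function(x, fs, trials = NULL,
                                      fit_range = c(70, 200), n_freqs = 40,
                                      n_cycles = 6, robust = TRUE,
                                      min_cycles = 2) {
  if (is.null(trials))
    trials <- trial_table(1L, length(x) + 1L)
  freqs <- seq(fit_range[1], fit_range[2], length.out = n_freqs)
  out <- list()
  for (ti in seq_len(nrow(trials))) {
    idx <- trials$start_sample[ti]:(trials$end_sample[ti] - 1L)
    if (length(idx) < 2 * fs / fit_range[1]) {
      warning(sprintf("trial %d shorter than 2 cycles of %g Hz; skipped",
                      ti, fit_range[1]))
      next
    }
    seg <- x[idx]
    tfr <- morlet_tfr(seg, fs, freqs, n_cycles, output = "power",
                      log = FALSE, buffer_s = 0)
    spec <- rowMeans(tfr$power[, , 1L])
    lf <- log10(freqs); lp <- log10(pmax(spec, .Machine$double.xmin))
    fit <- NULL
    if (robust)
      fit <- tryCatch(MASS::rlm(lp ~ lf, maxit = 50), error = function(e) NULL,
                      warning = function(w) NULL)
    if (is.null(fit)) fit <- stats::lm(lp ~ lf)
    bg <- as.numeric(stats::predict(fit, data.frame(lf = lf)))
    above <- lp > bg
    bands <- logical_runs(above)
    if (nrow(bands) == 0L) next
    for (b in seq_len(nrow(bands))) {
      flo <- freqs[bands[b, "start"]]; fhi <- freqs[bands[b, "end"]]
      if (bands[b, "start"] == bands[b, "end"]) {
        df <- diff(freqs[1:2]) / 2
        flo <- max(fit_range[1], flo - df); fhi <- min(fit_range[2], fhi + df)
      }
      bh <- band_filter_hilbert(seg, fs, c(flo, fhi))
      instf <- c(NA, diff(.unwrap(bh$phase))) * fs / (2 * pi)
      instf <- moving_average(stats::runmed(instf[-1L], .odd(round(0.01 * fs))),
                              round(0.01 * fs))
      instf <- c(instf[1L], instf)
      # keep samples whose band-mean wavelet power exceeds the 1/f fit level
      bsel <- freqs >= flo & freqs <= fhi
      thr <- mean(10^bg[bsel])
      act_series <- colMeans(tfr$power[, , 1L][bsel, , drop = FALSE])
      active <- as.vector(act_series > thr)
      eps <- logical_runs(active)
      if (nrow(eps) == 0L) next
      fc <- (flo + fhi) / 2
      min_len <- ceiling(min_cycles * fs / fc)
      for (e in seq_len(nrow(eps))) {
        len <- eps[e, "end"] - eps[e, "start"] + 1L
        if (len < min_len) next
        span <- eps[e, "start"]:eps[e, "end"]
        out[[length(out) + 1L]] <- data.frame(
          trial = ti, band_lo = flo, band_hi = fhi,
          start_sample = idx[1L] + eps[e, "start"] - 1L,
          end_sample = idx[1L] + eps[e, "end"],
          duration_ms = len / fs * 1000,
          center_freq = stats::median(instf[span], na.rm = TRUE))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(trial = integer(), band_lo = numeric(), band_hi = numeric(),
               start_sample = integer(), end_sample = integer(),
               duration_ms = numeric(), center_freq = numeric())
}

.unwrap <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1L], dp))
}

.odd <- function(k) if (k %% 2L == 0L) k + 1L else max(1L, k)

#' Synchronization metric across a grid of detection parameters
#'
#' Re-detects events on two channels for every combination of
#' minimum-duration and maximum-amplitude thresholds (identical parameters
#' on both channels) and computes the shift-predictor-normalized
#' synchronization metric for each setting.
#'
#' @param tsA,tsB single-channel [ts_recording()]s on the same clock.
#' @param trials a [trial_table()].
#' @param durations_ms minimum-duration thresholds to sweep, ms.
#' @param max_amps maximum-amplitude thresholds to sweep, SD.
#' @param envelope_threshold extent threshold used throughout the sweep
#'   (1 SD, the relaxed value, so all sweep settings see the same candidate
#'   pool).
#' @param band detection band, Hz.
#' @param max_lag_ms,bin_ms correlogram parameters.
#' @param window_ms synchronization window, ms.
#' @return list: `metric` (durations x amplitudes matrix), `counts_A`,
#'   `counts_B` (event counts per setting).
#' @export
detection_parameter_sweep <- function(tsA, tsB, trials,
                                      durations_ms = c(10, 20, 30, 40),
                                      max_amps = c(2, 3, 4),
                                      envelope_threshold = 1,
                                      band = c(80, 120),
                                      max_lag_ms = 200, bin_ms = 1,
                                      window_ms = 50) {
  m <- matrix(NA_real_, length(durations_ms), length(max_amps),
              dimnames = list(paste0(durations_ms, "ms"), paste0(max_amps, "sd")))
  cA <- cB <- m
  for (i in seq_along(durations_ms)) for (j in seq_along(max_amps)) {
    p <- detection_params(band = band,
                          envelope_threshold = min(envelope_threshold, max_amps[j]),
                          max_threshold = max_amps[j],
                          min_duration_ms = durations_ms[i])
    evA <- detect_ripples(tsA, p)
    evB <- detect_ripples(tsB, p)
    cA[i, j] <- nrow(evA); cB[i, j] <- nrow(evB)
    if (nrow(evA) && nrow(evB)) {
      truecc <- event_cross_correlogram(evA, evB, trials, tsA$fs,
                                        max_lag_ms, bin_ms)
      pred <- shift_predictor(evA, evB, trials, tsA$fs, max_lag_ms, bin_ms)
      m[i, j] <- tryCatch(
        synchronization_metric(truecc, pred, window_ms = window_ms),
        error = function(e) NA_real_)
    }
  }
  list(metric = m, counts_A = cA, counts_B = cB)
}
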