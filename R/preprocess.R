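# Recording clean-up: line-noise regression, local detrending, quartile-based
# trial rejection, transient-artifact masking, common average reference.

#' Regression-based line noise removal
#'
#' Fits and subtracts sinusoids at the target frequencies (60 and 120 Hz by
#' default) by least squares in sliding windows, tracking slow drift of the
#' mains amplitude. Windows are Hann-weighted with 50% overlap so that the
#' fitted component is reassembled smoothly (overlap-add, weights normalized
#' to one everywhere including the edges).
#'
#' @param ts a [ts_recording()].
#' @param freqs target frequencies, Hz.
#' @param window_s window length in seconds.
#' @return the cleaned [ts_recording()].
#' @export
remove_line_noise <- function(ts, freqs = c(60, 120), window_s = 10) {
  fs <- ts$fs
  if (any(freqs >= fs / 2)) stop("line frequency at or above Nyquist")
  n <- n_samples(ts)
  wlen <- min(n, round(window_s * fs))
  step <- max(1L, wlen %/% 2L)
  starts <- unique(c(seq(1L, max(1L, n - wlen + 1L), by = step), n - wlen + 1L))
  hann <- sin(pi * (seq_len(wlen) - 0.5) / wlen)^2
  tt <- seq_len(n) / fs
  basis <- do.call(cbind, lapply(freqs, function(f)
    cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))))
  out <- ts
  for (ch in seq_len(n_channels(ts))) {
    x <- ts$data[ch, ]
    fitted <- numeric(n)
    wsum <- numeric(n)
    for (s0 in starts) {
      idx <- s0:(s0 + wlen - 1L)
      b <- basis[idx, , drop = FALSE]
      cf <- stats::lm.fit(b, x[idx])$coefficients
      cf[is.na(cf)] <- 0
      fitted[idx] <- fitted[idx] + (b %*% cf) * hann
      wsum[idx] <- wsum[idx] + hann
    }
    ok <- wsum > 1e-12
    fitted[ok] <- fitted[ok] / wsum[ok]
    out$data[ch, ] <- x - fitted
  }
  out
}

#' Local detrending (removal of slow fluctuations)
#'
#' Subtracts a zero-phase low-pass (Butterworth, applied forward-backward)
#' running fit from each channel, removing fluctuations at or below `cutoff`
#' while leaving the 10-200 Hz range essentially untouched.
#'
#' @param ts a [ts_recording()].
#' @param cutoff low-pass corner frequency, Hz.
#' @param order Butterworth design order.
#' @return the detrended [ts_recording()].
#' @export
detrend_slow <- function(ts, cutoff = 2, order = 2) {
  bf <- signal::butter(order, cutoff / (ts$fs / 2), type = "low")
  out <- ts
  for (ch in seq_len(n_channels(ts))) {
    x <- ts$data[ch, ]
    out$data[ch, ] <- x - signal::filtfilt(bf, x - mean(x)) - mean(x)
  }
  out
}

#' Quartile-based rejection of outlier trials
#'
#' Computes a per-trial voltage statistic, sorts it, forms the quartile
#' boundaries Q1 and Q3, and excludes every trial whose statistic exceeds
#' `Q3 + w * (Q3 - Q1)` (strict inequality, so when all trials are equal the
#' threshold equals the common value and every trial is kept). The per-trial
#' statistic is the mean absolute voltage within the trial, computed per
#' channel and aggregated across channels by the maximum — raw signed means
#' cancel and cannot index artifact severity (see the methods vignette); set
#' `stat_fun` for an alternative.
#'
#' @param ts a [ts_recording()].
#' @param trials a [trial_table()].
#' @param w outlier weight (2.3 by default).
#' @param stat_fun function(matrix channels x samples) -> scalar per-trial
#'   statistic; defaults to max over channels of mean absolute voltage.
#' @return integer vector of surviving trial indices.
#' @export
reject_outlier_trials <- function(ts, trials, w = 2.3, stat_fun = NULL) {
  if (nrow(trials) < 4L) stop("need at least 4 trials to form quartiles")
  if (is.null(stat_fun))
    stat_fun <- function(m) max(rowMeans(abs(m)))
  stat <- vapply(seq_len(nrow(trials)), function(i) {
    idx <- trials$start_sample[i]:(trials$end_sample[i] - 1L)
    idx <- idx[idx >= 1L & idx <= n_samples(ts)]
    stat_fun(ts$data[, idx, drop = FALSE])
  }, numeric(1))
  q <- stats::quantile(stat, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + w * (q[2] - q[1])
  which(stat <= thr)
}

#' Artifact mask
#'
#' Internal constructor for the per-channel boolean artifact mask. Every
#' flagged seed sample is surrounded by at least 100 ms of flagged samples on
#' each side (clipped at the recording edges).
#'
#' @param mask logical matrix, channels x samples.
#' @param reason character tag per channel.
#' @return an object of class `artifact_mask`.
#' @keywords internal
artifact_mask <- function(mask, reason) {
  structure(list(mask = mask, reason = reason), class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d channel(s) x %d samples, %.2f%% flagged\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Mask sharp transients and high-frequency artifacts
#'
#' Per channel, z-scores (a) the signal gradient (first difference) and
#' (b) the instantaneous amplitude of the signal high-passed above 250 Hz,
#' flags every sample at which either z-score exceeds `z_thresh`, and
#' dilates the flags by +/- `dilate_ms` (clipped at the edges). This is the
#' detector used to exclude interictal discharges and movement artifacts.
#'
#' @param ts a [ts_recording()]; sampling rate must be at least 600 Hz so
#'   the 250 Hz high-pass is below Nyquist.
#' @param z_thresh z-score threshold (5 by default).
#' @param dilate_ms dilation radius, ms.
#' @param hp_freq high-pass corner for the high-frequency amplitude, Hz.
#' @return an `artifact_mask`.
#' @export
mask_transient_artifacts <- function(ts, z_thresh = 5, dilate_ms = 100,
                                     hp_freq = 250) {
  fs <- ts$fs
  if (fs < 2.4 * hp_freq) stop("sampling rate too low for the high-pass stage")
  bf <- signal::butter(2, hp_freq / (fs / 2), type = "high")
  radius <- round(dilate_ms / 1000 * fs)
  n <- n_samples(ts)
  mask <- matrix(FALSE, n_channels(ts), n,
                 dimnames = list(rownames(ts$data), NULL))
  reason <- character(n_channels(ts))
  for (ch in seq_len(n_channels(ts))) {
    x <- ts$data[ch, ]
    grad <- c(0, diff(x))
    zg <- abs(zscore(grad))
    hf <- Mod(analytic_signal(signal::filtfilt(bf, x)))
    zh <- abs(zscore(hf))
    seeds_g <- zg > z_thresh
    seeds_h <- zh > z_thresh
    mask[ch, ] <- dilate_logical(seeds_g | seeds_h, radius)
    reason[ch] <- paste(c("gradient", "hf_amplitude")[c(any(seeds_g), any(seeds_h))],
                        collapse = "+")
  }
  artifact_mask(mask, reason)
}

#' Common average reference
#'
#' Subtracts the per-sample mean across retained channels from every channel,
#' approximating a reference-free montage. The output has zero cross-channel
#' mean at every sample, and the operation is idempotent.
#'
#' @param ts a [ts_recording()] with at least two channels.
#' @return re-referenced [ts_recording()].
#' @export
common_average_reference <- function(ts) {
  if (n_channels(ts) < 2L) stop("common average reference needs >= 2 channels")
  out <- ts
  out$data <- sweep(ts$data, 2L, colMeans(ts$data))
  out
}
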