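# Spike-derived continuous measures and waveform quality.

#' Smoothed instantaneous spike rate
#'
#' Convolves the spike raster with a unit-integral Gaussian kernel
#' (sigma = 25 ms by default, truncated at +/- 5 sigma, edges handled by
#' reflection so that total rate mass equals the spike count). Optionally
#' z-scores the rate by its mean and standard deviation over the entire
#' session.
#'
#' @param train a [spike_train()].
#' @param n_samples session length in samples.
#' @param sigma_ms kernel SD, ms.
#' @param zscore z-score over the session?
#' @return numeric rate vector (Hz, or z-units when `zscore = TRUE`).
#' @export
smoothed_spike_rate <- function(train, n_samples, sigma_ms = 25,
                                zscore = FALSE) {
  if (sigma_ms <= 0) stop("sigma must be positive")
  fs <- train$fs
  delta <- numeric(n_samples)
  s <- train$samples[train$samples >= 1L & train$samples <= n_samples]
  if (length(s)) {
    tab <- tabulate(s, nbins = n_samples)
    delta <- tab
  }
  kern <- gaussian_kernel(sigma_ms / 1000, fs)
  rate <- conv_reflect(delta, kern) * sum(kern)
  if (zscore) rate <- (rate - mean(rate)) / stats::sd(rate)
  rate
}

#' Waveform signal-to-noise ratio
#'
#' `SNR = (Vpeak - Vtrough) / (Noise * C)` where `Vpeak` and `Vtrough` are
#' the maximum and minimum of the mean waveform, `Noise` is the standard
#' deviation of all waveform residuals (each waveform minus the mean,
#' concatenated into one long vector — the within-unit variability in
#' waveform shape), and `C` is a scaling factor, 5 by default. SNR is
#' invariant to rescaling all waveforms by a common positive factor.
#'
#' @param waveforms numeric matrix, spikes x samples (at least 2 spikes).
#' @param C scaling factor.
#' @return scalar SNR.
#' @export
waveform_snr <- function(waveforms, C = 5) {
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) < 2L) stop("need at least 2 waveforms")
  mw <- colMeans(waveforms)
  resid <- sweep(waveforms, 2L, mw)
  noise <- stats::sd(as.vector(t(resid)))
  if (!is.finite(noise) || noise == 0)
    stop("identical waveforms: noise term is zero, SNR undefined")
  (max(mw) - min(mw)) / (noise * C)
}
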