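# Time-frequency decomposition: Morlet wavelet power/phase, high-frequency
# activity (HFA), and band-limited Hilbert amplitude/phase.

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves each channel with complex Morlet wavelets (default: 200 linearly
#' spaced frequencies between 2 and 200 Hz, 6 cycles) via frequency-domain
#' multiplication with one-sided Gaussian kernels, so the per-frequency
#' output is an analytic signal carrying both power and phase. Wavelets are
#' energy-normalized (unit L2 norm in continuous time); power is the squared
#' magnitude, log-transformed by default to give a continuous instantaneous
#' power measure. An edge buffer (1000 ms by default) is recorded and
#' excluded from all statistics computed downstream (z-scoring, HFA).
#'
#' @param ts a [ts_recording()] or numeric vector.
#' @param fs sampling rate (ignored when `ts` is a recording).
#' @param freqs frequency grid, Hz; all must be below Nyquist.
#' @param n_cycles wavelet number (cycles; width parameter).
#' @param output `"power"`, `"phase"` or `"both"`.
#' @param log log-transform power?
#' @param buffer_s edge buffer excluded from statistics, s.
#' @return object of class `tfr`: list with `power` and/or `phase` arrays of
#'   dimension frequencies x samples x channels, plus `freqs`, `fs`, `log`,
#'   `zscored`, `buffer_samples`.
#' @export
morlet_tfr <- function(ts, fs = NULL, freqs = seq(2, 200, length.out = 200),
                       n_cycles = 6, output = c("power", "phase", "both"),
                       log = TRUE, buffer_s = 1) {
  output <- match.arg(output)
  if (inherits(ts, "ts_recording")) {
    dat <- ts$data; fs <- ts$fs
  } else {
    dat <- matrix(ts, nrow = 1L)
  }
  if (is.null(fs)) stop("fs required for vector input")
  if (max(freqs) >= fs / 2) stop("wavelet frequency at or above Nyquist")
  n <- ncol(dat); nch <- nrow(dat); nf <- length(freqs)
  fgrid <- seq(0, fs, length.out = n + 1L)[-(n + 1L)]
  pos <- fgrid <= fs / 2
  want_pow <- output %in% c("power", "both")
  want_ph <- output %in% c("phase", "both")
  pow <- if (want_pow) array(NA_real_, c(nf, n, nch)) else NULL
  ph <- if (want_ph) array(NA_real_, c(nf, n, nch)) else NULL
  for (ch in seq_len(nch)) {
    X <- stats::fft(dat[ch, ])
    for (k in seq_len(nf)) {
      f <- freqs[k]
      sigma_t <- n_cycles / (2 * pi * f)
      sigma_f <- 1 / (2 * pi * sigma_t)
      G <- numeric(n)
      G[pos] <- (4 * pi * sigma_t^2)^(1 / 4) *
        exp(-(fgrid[pos] - f)^2 / (2 * sigma_f^2))
      cc <- stats::fft(X * G, inverse = TRUE) / n
      if (want_pow) {
        p <- Mod(cc)^2
        pow[k, , ch] <- if (log) base::log(pmax(p, .Machine$double.xmin)) else p
      }
      if (want_ph) ph[k, , ch] <- Arg(cc)
    }
  }
  structure(list(power = pow, phase = ph, freqs = freqs, fs = fs,
                 log = log, zscored = FALSE,
                 buffer_samples = round(buffer_s * fs)),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power %||% x$phase)
  cat(sprintf("<tfr> %d frequencies (%.3g-%.3g Hz) x %d samples x %d channel(s)%s%s\n",
              d[1], min(x$freqs), max(x$freqs), d[2], d[3],
              if (x$zscored) ", z-scored" else "",
              if (isTRUE(x$log)) ", log power" else ""))
  invisible(x)
}

#' Z-score wavelet power separately for each frequency
#'
#' Uses the mean and standard deviation of all samples of the session for
#' that frequency and channel, excluding the edge buffers, so that power is
#' comparable across frequencies and sessions.
#'
#' @param tfr a `tfr` with power.
#' @return the `tfr` with z-scored power.
#' @export
zscore_tfr <- function(tfr) {
  if (is.null(tfr$power)) stop("tfr carries no power")
  n <- dim(tfr$power)[2]
  b <- min(tfr$buffer_samples, (n - 1L) %/% 2L)
  interior <- (b + 1L):(n - b)
  for (ch in seq_len(dim(tfr$power)[3])) {
    m <- rowMeans(tfr$power[, interior, ch, drop = FALSE])
    s <- apply(tfr$power[, interior, ch, drop = FALSE], 1L, stats::sd)
    s[s == 0] <- 1
    tfr$power[, , ch] <- (tfr$power[, , ch] - m) / s
  }
  tfr$zscored <- TRUE
  tfr
}

#' High-frequency activity (HFA) time series
#'
#' Mean of z-scored power over the band frequencies (70-200 Hz by default),
#' temporally smoothed with a sliding window (600 ms, 90% overlap by
#' default); the output sampling interval is the window step. Samples listed
#' in `exclude_samples` are dropped from the window means — this is the
#' mechanism used by the ripple-removal control, which excises the time
#' indices of detected ripples and recomputes HFA.
#'
#' @param tfr a z-scored `tfr`.
#' @param band frequency band, Hz.
#' @param window_ms smoothing window, ms.
#' @param overlap fractional window overlap in [0, 1).
#' @param exclude_samples optional integer vector of sample indices excluded
#'   from the averages.
#' @return list with `time_s` (window centers) and `hfa` (channels x windows
#'   matrix; `NA` where a window is fully excluded).
#' @export
hfa_timeseries <- function(tfr, band = c(70, 200), window_ms = 600,
                           overlap = 0.9, exclude_samples = NULL) {
  if (!isTRUE(tfr$zscored)) stop("hfa_timeseries expects z-scored power")
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) stop("band outside the frequency grid")
  n <- dim(tfr$power)[2]
  nch <- dim(tfr$power)[3]
  fs <- tfr$fs
  wlen <- max(1L, round(window_ms / 1000 * fs))
  step <- max(1L, round(wlen * (1 - overlap)))
  b <- min(tfr$buffer_samples, (n - 1L) %/% 2L)
  starts <- seq(b + 1L, n - b - wlen + 1L, by = step)
  if (!length(starts)) stop("recording shorter than one window")
  keep <- rep(TRUE, n)
  if (length(exclude_samples)) keep[exclude_samples] <- FALSE
  hfa <- matrix(NA_real_, nch, length(starts))
  for (ch in seq_len(nch)) {
    series <- colMeans(tfr$power[sel, , ch, drop = FALSE])
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + wlen - 1L)
      idx <- idx[keep[idx]]
      if (length(idx)) hfa[ch, w] <- mean(series[idx])
    }
  }
  list(time_s = (starts + (wlen - 1L) / 2 - 1L) / fs, hfa = hfa,
       window_samples = wlen, step_samples = step)
}

#' Band-limited instantaneous amplitude and phase
#'
#' Band-passes the signal with a zero-phase Butterworth filter (second-order
#' design, applied forward-backward) and extracts the instantaneous
#' amplitude and phase of the analytic signal. Phase follows the
#' `x = A*cos(phi)` convention: the oscillation trough is at phase pi.
#'
#' @param x numeric vector or [ts_recording()].
#' @param fs sampling rate (ignored for recordings).
#' @param band `c(low, high)` in Hz, within (0, Nyquist).
#' @param order Butterworth design order.
#' @return for a vector: list with `analytic`, `amplitude`, `phase`,
#'   `filtered`; for a recording: list with `amplitude`, `phase`, `filtered`
#'   matrices (channels x samples).
#' @export
band_filter_hilbert <- function(x, fs = NULL, band, order = 2) {
  if (inherits(x, "ts_recording")) {
    fs <- x$fs
    bf <- .design_bandpass(fs, band, order)
    amp <- ph <- filt <- matrix(0, n_channels(x), n_samples(x),
                                dimnames = dimnames(x$data))
    for (ch in seq_len(n_channels(x))) {
      f <- signal::filtfilt(bf, x$data[ch, ])
      a <- analytic_signal(f)
      amp[ch, ] <- Mod(a); ph[ch, ] <- Arg(a); filt[ch, ] <- f
    }
    return(list(amplitude = amp, phase = ph, filtered = filt, fs = fs, band = band))
  }
  if (is.null(fs)) stop("fs required for vector input")
  bf <- .design_bandpass(fs, band, order)
  f <- signal::filtfilt(bf, x)
  a <- analytic_signal(f)
  list(analytic = a, amplitude = Mod(a), phase = Arg(a), filtered = f,
       fs = fs, band = band)
}

.design_bandpass <- function(fs, band, order) {
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high < Nyquist")
  signal::butter(order, band / (fs / 2), type = "pass")
}
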