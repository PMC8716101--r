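# Phase-locking machinery: pairwise phase consistency (PPC), Rayleigh tests,
# spike-field PPC spectra with trial-shuffle z-scoring, condition contrasts
# with spike-count-matched subsampling, across-channel ripple alignment PPC,
# and spike-triggered averages.

# Fast PPC of a phase vector via the unit-vector identity:
#   gamma = 2/(N(N-1)) * sum_{j<k} cos(theta_j - theta_k)
#         = (|sum_j exp(i theta_j)|^2 - N) / (N (N-1))
.ppc_val <- function(phases) {
  N <- length(phases)
  s <- sum(complex(argument = phases))
  (Mod(s)^2 - N) / (N * (N - 1))
}

# PPC for a matrix of phases (rows = frequency/time, columns = observations):
# one pass over columns, vectorized over rows.
.ppc_rows <- function(phase_mat) {
  N <- ncol(phase_mat)
  s <- rowSums(exp(1i * phase_mat))
  (Mod(s)^2 - N) / (N * (N - 1))
}

#' Pairwise phase consistency (PPC)
#'
#' The mean pairwise cosine of phase differences — a bias-free measure of
#' phase concentration whose population value equals the squared
#' phase-locking value. Computed through the unit-vector identity, which is
#' algebraically equal to the explicit double loop over all pairs. Also
#' returns the average pairwise circular distance (APCD, the mean absolute
#' angular distance modulo pi over all pairs) and the preferred phase (the
#' angle of the resultant vector).
#'
#' For N observations the estimator is bounded in `[-1/(N-1), 1]`, reaching
#' 1 only when all phases coincide.
#'
#' @param phases numeric vector of phases in radians (N >= 2); values are
#'   wrapped into (-pi, pi].
#' @return object of class `ppc_result`: list with `ppc`, `n`, `apcd`,
#'   `preferred_phase`.
#' @export
ppc <- function(phases) {
  N <- length(phases)
  if (N < 2L) stop("PPC requires at least 2 phases")
  phases <- wrap_phase(phases)
  d <- abs(outer(phases, phases, "-"))
  apcd <- sum((d %% pi)[upper.tri(d)]) * 2 / (N * (N - 1))
  structure(list(ppc = .ppc_val(phases), n = N, apcd = apcd,
                 preferred_phase = Arg(sum(complex(argument = phases)))),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("<ppc_result> ppc = %.4f (n = %d), APCD = %.4f, preferred phase = %.3f rad\n",
              x$ppc, x$n, x$apcd, x$preferred_phase))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Resultant length `Rbar = |sum exp(i theta)| / n` with the standard
#' finite-n approximation for the p-value
#' (`p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, `R = n * Rbar`).
#'
#' @param phases numeric vector of phases (n >= 2).
#' @return list with `r_bar`, `n`, `p`, `preferred_phase`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2L) stop("Rayleigh test requires at least 2 phases")
  s <- sum(complex(argument = phases))
  r_bar <- Mod(s) / n
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r_bar = r_bar, n = n, p = min(1, p), preferred_phase = Arg(s))
}

# Phase of each channel at a frequency grid: list of nf x n matrices per
# channel (Morlet), computed lazily for the channels requested.
.channel_phases <- function(lfp, channels, freqs, n_cycles = 6) {
  out <- vector("list", max(channels))
  for (ch in unique(channels)) {
    tfr <- morlet_tfr(lfp$data[ch, ], lfp$fs, freqs, n_cycles,
                      output = "phase", buffer_s = 0)
    out[[ch]] <- tfr$phase[, , 1L]
  }
  out
}

#' Spike-field PPC spectrum
#'
#' For every unit, extracts the LFP phase of the unit's channel at each
#' spike time for each frequency (Morlet, 60 log-spaced frequencies between
#' 2 and 400 Hz by default), computes PPC per trial (trials contributing at
#' least `min_spikes_trial` spikes), and averages across trials to give one
#' spectrum per unit; the participant-level spectrum is the average across
#' units. Set `pool_trials = TRUE` to aggregate spikes across trials before
#' computing PPC (used for condition contrasts where per-trial counts are
#' low).
#'
#' @param trains list of [spike_train()] (each with a `channel`).
#' @param lfp an [ts_recording()] at the micro scale.
#' @param trials a [trial_table()].
#' @param freqs frequency grid, Hz.
#' @param n_cycles wavelet number.
#' @param min_spikes_trial minimum spikes for a trial to contribute.
#' @param pool_trials aggregate spikes across trials before PPC?
#' @param phases optional precomputed per-channel phase matrices (from an
#'   earlier call; avoids re-convolution).
#' @return list: `freqs`, `per_unit` (units x frequencies PPC matrix),
#'   `spectrum` (mean across units), `units`, `phases` (reusable).
#' @export
spike_field_ppc_spectrum <- function(trains, lfp, trials,
                                     freqs = exp(seq(log(2), log(400),
                                                     length.out = 60)),
                                     n_cycles = 6, min_spikes_trial = 2,
                                     pool_trials = FALSE, phases = NULL) {
  freqs <- freqs[freqs < lfp$fs / 2]
  chs <- vapply(trains, function(tr) as.integer(tr$channel), integer(1))
  if (is.null(phases)) phases <- .channel_phases(lfp, chs, freqs, n_cycles)
  per_unit <- matrix(NA_real_, length(trains), length(freqs))
  kept <- logical(length(trains))
  for (ui in seq_along(trains)) {
    tr <- trains[[ui]]
    P <- phases[[chs[ui]]]
    if (pool_trials) {
      s <- tr$samples[.in_any_trial(tr$samples, trials)]
      if (length(s) >= 2L) {
        per_unit[ui, ] <- .ppc_rows(P[, s, drop = FALSE])
        kept[ui] <- TRUE
      }
    } else {
      vals <- NULL
      for (ti in seq_len(nrow(trials))) {
        s <- tr$samples[tr$samples >= trials$start_sample[ti] &
                          tr$samples < trials$end_sample[ti]]
        if (length(s) < min_spikes_trial || length(s) < 2L) next
        v <- .ppc_rows(P[, s, drop = FALSE])
        vals <- cbind(vals, v)
      }
      if (!is.null(vals)) {
        per_unit[ui, ] <- rowMeans(vals)
        kept[ui] <- TRUE
      }
    }
  }
  if (any(!kept))
    message(sprintf("spike_field_ppc_spectrum: %d unit(s) without qualifying trials excluded",
                    sum(!kept)))
  list(freqs = freqs,
       per_unit = per_unit[kept, , drop = FALSE],
       spectrum = colMeans(per_unit[kept, , drop = FALSE]),
       units = vapply(trains, function(tr) as.character(tr$unit),
                      character(1))[kept],
       phases = phases)
}

.in_any_trial <- function(samples, trials) {
  ok <- rep(FALSE, length(samples))
  for (ti in seq_len(nrow(trials)))
    ok <- ok | (samples >= trials$start_sample[ti] &
                  samples < trials$end_sample[ti])
  ok
}

#' Z-score a PPC spectrum against a trial-shuffle null
#'
#' The null pairs the spikes of each trial with the LFP of a randomly chosen
#' other trial (same within-trial offsets), recomputes the across-unit mean
#' PPC spectrum `n_shuffle` times, and z-scores the observed spectrum by the
#' null mean and SD per frequency.
#'
#' @param trains,lfp,trials,freqs,n_cycles as in
#'   [spike_field_ppc_spectrum()].
#' @param n_shuffle number of shuffles.
#' @param min_spikes_trial minimum spikes per contributing trial.
#' @param seed RNG seed (fixed seed gives bit-identical output).
#' @param phases optional precomputed phases.
#' @return list: `freqs`, `z`, `observed`, `null_mean`, `null_sd`.
#' @export
zscore_ppc_by_trial_shuffle <- function(trains, lfp, trials,
                                        freqs = exp(seq(log(2), log(400),
                                                        length.out = 60)),
                                        n_cycles = 6, n_shuffle = 100,
                                        min_spikes_trial = 2, seed = 1L,
                                        phases = NULL) {
  if (nrow(trials) < 2L) stop("trial shuffle needs >= 2 trials")
  freqs <- freqs[freqs < lfp$fs / 2]
  obs <- spike_field_ppc_spectrum(trains, lfp, trials, freqs, n_cycles,
                                  min_spikes_trial, phases = phases)
  phases <- obs$phases
  set.seed(seed)
  null <- matrix(NA_real_, n_shuffle, length(freqs))
  lens <- trials$end_sample - trials$start_sample
  for (b in seq_len(n_shuffle)) {
    perm <- sample.int(nrow(trials))
    sh_trains <- lapply(trains, function(tr) {
      s_new <- integer(0)
      for (ti in seq_len(nrow(trials))) {
        s <- tr$samples[tr$samples >= trials$start_sample[ti] &
                          tr$samples < trials$end_sample[ti]]
        if (!length(s)) next
        off <- (s - trials$start_sample[ti]) %% lens[perm[ti]]
        s_new <- c(s_new, trials$start_sample[perm[ti]] + off)
      }
      tr$samples <- sort(unique(s_new))
      tr
    })
    sp <- suppressMessages(
      spike_field_ppc_spectrum(sh_trains, lfp, trials, freqs, n_cycles,
                               min_spikes_trial, phases = phases))
    null[b, ] <- sp$spectrum
  }
  nm <- colMeans(null)
  nsd <- apply(null, 2L, stats::sd)
  if (any(!is.finite(nsd)) || any(nsd == 0))
    stop("degenerate shuffle null (zero SD)")
  list(freqs = freqs, z = (obs$spectrum - nm) / nsd, observed = obs$spectrum,
       null_mean = nm, null_sd = nsd)
}

#' Compare PPC between two spike conditions
#'
#' Computes raw (not z-scored) PPC per unit per frequency for two spike
#' conditions (e.g. spikes inside vs outside detected ripples), aggregating
#' spikes across trials. Units must contribute at least `min_spikes` spikes
#' to each condition; the larger-count condition is randomly subsampled to
#' the smaller count, `n_subsample` times, and the average PPC over
#' iterations is assigned to it, so spike-count bias cannot favour either
#' condition. When counts are equal no subsampling is performed.
#'
#' @param trains list of [spike_train()].
#' @param lfp an [ts_recording()].
#' @param condA_samples,condB_samples lists (one element per unit) of spike
#'   sample indices belonging to each condition.
#' @param freqs frequency grid, Hz.
#' @param n_cycles wavelet number.
#' @param min_spikes minimum spikes per condition per unit.
#' @param n_subsample subsampling iterations.
#' @param seed RNG seed.
#' @param phases optional precomputed phases.
#' @return list: `freqs`, `ppc_A`, `ppc_B` (units x frequencies), `delta`
#'   (A - B), `mean_delta`, `units_kept` (logical).
#' @export
compare_ppc_conditions <- function(trains, lfp, condA_samples, condB_samples,
                                   freqs = exp(seq(log(2), log(400),
                                                   length.out = 60)),
                                   n_cycles = 6, min_spikes = 10,
                                   n_subsample = 200, seed = 1L,
                                   phases = NULL) {
  freqs <- freqs[freqs < lfp$fs / 2]
  chs <- vapply(trains, function(tr) as.integer(tr$channel), integer(1))
  if (is.null(phases)) phases <- .channel_phases(lfp, chs, freqs, n_cycles)
  set.seed(seed)
  nf <- length(freqs)
  keep <- logical(length(trains))
  pA <- pB <- matrix(NA_real_, length(trains), nf)
  for (ui in seq_along(trains)) {
    a <- condA_samples[[ui]]; b <- condB_samples[[ui]]
    if (length(a) < min_spikes || length(b) < min_spikes) next
    keep[ui] <- TRUE
    P <- phases[[chs[ui]]]
    target <- min(length(a), length(b))
    sub_ppc <- function(s) {
      if (length(s) == target) return(.ppc_rows(P[, s, drop = FALSE]))
      acc <- numeric(nf)
      for (it in seq_len(n_subsample))
        acc <- acc + .ppc_rows(P[, sample(s, target), drop = FALSE])
      acc / n_subsample
    }
    pA[ui, ] <- sub_ppc(a)
    pB[ui, ] <- sub_ppc(b)
  }
  if (!any(keep)) stop("no unit meets the minimum spike count in both conditions")
  pA <- pA[keep, , drop = FALSE]; pB <- pB[keep, , drop = FALSE]
  list(freqs = freqs, ppc_A = pA, ppc_B = pB, delta = pA - pB,
       mean_delta = colMeans(pA - pB), units_kept = keep)
}

#' Across-channel ripple alignment PPC
#'
#' For each macro-scale (iEEG) ripple, treats every time point within the
#' event as an observation: at each sample the ripple-band phases of all
#' micro-array channels form a phase set whose PPC measures how aligned the
#' micro-scale oscillations are; the event value is the maximum PPC over the
#' event's samples. Optionally restricts the channel set, per event, to
#' channels with a concurrently detected LFP ripple.
#'
#' @param ieeg_events `ripple_events` detected at the macro scale.
#' @param mea_phase channels x samples matrix of ripple-band phases (from
#'   [band_filter_hilbert()] on the micro-array recording).
#' @param lfp_events optional `ripple_events` at the micro scale; when
#'   given, only channels whose LFP events overlap the iEEG event are used
#'   (events with fewer than 2 such channels yield `NA`).
#' @return data.frame: event, n_channels, max_ppc, peak_sample.
#' @export
ripple_alignment_ppc <- function(ieeg_events, mea_phase, lfp_events = NULL) {
  if (nrow(mea_phase) < 2L) stop("alignment PPC needs >= 2 micro channels")
  out <- data.frame(event = seq_len(nrow(ieeg_events)),
                    n_channels = NA_integer_, max_ppc = NA_real_,
                    peak_sample = NA_integer_)
  for (i in seq_len(nrow(ieeg_events))) {
    span <- ieeg_events$start_sample[i]:(ieeg_events$end_sample[i] - 1L)
    span <- span[span >= 1L & span <= ncol(mea_phase)]
    chans <- seq_len(nrow(mea_phase))
    if (!is.null(lfp_events)) {
      has <- vapply(chans, function(ch) {
        ev <- lfp_events[lfp_events$channel == ch, , drop = FALSE]
        any(ev$start_sample <= span[length(span)] & ev$end_sample - 1L >= span[1L])
      }, logical(1))
      chans <- chans[has]
    }
    N <- length(chans)
    out$n_channels[i] <- N
    if (N < 2L || !length(span)) next
    S <- colSums(exp(1i * mea_phase[chans, span, drop = FALSE]))
    vals <- (Mod(S)^2 - N) / (N * (N - 1))
    out$max_ppc[i] <- max(vals)
    out$peak_sample[i] <- span[which.max(vals)]
  }
  out
}

#' Spike-triggered average of a signal
#'
#' Mean of signal segments centered on spike times, optionally after
#' band-pass filtering (e.g. 2-10 Hz to expose locking to slow deflections)
#' and optionally restricted to spikes inside or outside a set of events.
#'
#' @param trains a [spike_train()] or list of them (pooled).
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param window_ms half-window, ms (the STA spans +/- `window_ms`).
#' @param filter_band optional `c(low, high)` band-pass applied to `x`.
#' @param events optional `ripple_events` used with `restrict`.
#' @param restrict `"all"`, `"inside"` or `"outside"` events.
#' @return list: `lag_s`, `sta`, `n_spikes`.
#' @export
spike_triggered_average <- function(trains, x, fs, window_ms = 200,
                                    filter_band = NULL, events = NULL,
                                    restrict = c("all", "inside", "outside")) {
  restrict <- match.arg(restrict)
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (!is.null(filter_band))
    x <- band_filter_hilbert(x, fs, filter_band)$filtered
  half <- round(window_ms / 1000 * fs)
  n <- length(x)
  spikes <- sort(unlist(lapply(trains, function(tr) tr$samples)))
  if (restrict != "all") {
    if (is.null(events)) stop("events required for restricted STA")
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(events)))
      inside[events$start_sample[i]:(events$end_sample[i] - 1L)] <- TRUE
    spikes <- spikes[if (restrict == "inside") inside[spikes] else !inside[spikes]]
  }
  spikes <- spikes[spikes - half >= 1L & spikes + half <= n]
  if (!length(spikes)) stop("no qualifying spikes for the STA")
  acc <- numeric(2L * half + 1L)
  for (s in spikes) acc <- acc + x[(s - half):(s + half)]
  list(lag_s = (-half:half) / fs, sta = acc / length(spikes),
       n_spikes = length(spikes))
}
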