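# Event-level statistics: cross-correlograms with shift predictors and
# circular-shift chance distributions, synchronization / coincidence / burst
# metrics, windowed amplitude-rate correlations, and Fisher's z.

.ccg_bins <- function(max_lag_ms, bin_ms) {
  edges <- seq(-max_lag_ms - bin_ms / 2, max_lag_ms + bin_ms / 2, by = bin_ms)
  list(edges = edges, centers = (edges[-1L] + edges[-length(edges)]) / 2)
}

.hist_lags <- function(diffs_ms, bins) {
  nb <- length(bins$centers)
  if (!length(diffs_ms)) return(numeric(nb))
  bw <- bins$edges[2L] - bins$edges[1L]
  d <- diffs_ms[diffs_ms >= bins$edges[1L] & diffs_ms < bins$edges[nb + 1L]]
  if (!length(d)) return(numeric(nb))
  idx <- pmin(nb, floor((d - bins$edges[1L]) / bw) + 1L)
  as.numeric(tabulate(idx, nbins = nb))
}

.correlogram <- function(lags_ms, counts, n_pairs, normalization) {
  structure(list(lags_ms = lags_ms, counts = counts, n_pairs = n_pairs,
                 normalization = normalization), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d bins (%.0f..%.0f ms), %g pairs, %s\n",
              length(x$lags_ms), min(x$lags_ms), max(x$lags_ms),
              x$n_pairs, x$normalization))
  invisible(x)
}

#' Cross-correlogram of event peak times
#'
#' Histogram of peak-time differences (B relative to A) between events of
#' the same trial, pooled across trials. When `eventsA` and `eventsB` are
#' the identical table, self-pairs (an event against itself) are excluded,
#' making the result an auto-correlogram.
#'
#' @param eventsA,eventsB `ripple_events` tables sharing the session clock.
#' @param trials a [trial_table()].
#' @param fs sampling rate, Hz.
#' @param max_lag_ms maximum lag, ms.
#' @param bin_ms bin width, ms.
#' @return a `correlogram`.
#' @export
event_cross_correlogram <- function(eventsA, eventsB, trials, fs,
                                    max_lag_ms = 200, bin_ms = 1) {
  if (nrow(eventsA) == 0L || nrow(eventsB) == 0L)
    warning("empty event set: zero correlogram")
  same <- identical(eventsA, eventsB)
  bins <- .ccg_bins(max_lag_ms, bin_ms)
  counts <- numeric(length(bins$centers))
  n_pairs <- 0
  for (ti in seq_len(nrow(trials))) {
    a <- which(eventsA$peak_sample >= trials$start_sample[ti] &
                 eventsA$peak_sample < trials$end_sample[ti])
    b <- which(eventsB$peak_sample >= trials$start_sample[ti] &
                 eventsB$peak_sample < trials$end_sample[ti])
    if (!length(a) || !length(b)) next
    d <- outer(eventsB$peak_sample[b], eventsA$peak_sample[a], "-") / fs * 1000
    if (same) {
      self <- outer(b, a, "==")
      d <- d[!self]
    }
    counts <- counts + .hist_lags(as.numeric(d), bins)
    n_pairs <- n_pairs + length(d)
  }
  .correlogram(bins$centers, counts, n_pairs, "raw")
}

#' Shift predictor of a cross-correlogram
#'
#' The chance cross-correlogram expected from stimulus-locked but
#' trial-independent coincidence: for each trial, the A events of that trial
#' (times relative to trial onset) are cross-correlated with the B events of
#' every *other* trial, the n-1 correlograms are averaged, and the per-trial
#' predictors are summed so the result is on the same scale as the pooled
#' true correlogram. Permuting trial order leaves the predictor unchanged.
#'
#' @inheritParams event_cross_correlogram
#' @return a `correlogram` with normalization `"shift_predictor"`.
#' @export
shift_predictor <- function(eventsA, eventsB, trials, fs,
                            max_lag_ms = 200, bin_ms = 1) {
  nt <- nrow(trials)
  if (nt < 2L) stop("shift predictor requires >= 2 trials")
  bins <- .ccg_bins(max_lag_ms, bin_ms)
  relA <- relB <- vector("list", nt)
  for (ti in seq_len(nt)) {
    relA[[ti]] <- (eventsA$peak_sample[eventsA$peak_sample >= trials$start_sample[ti] &
                                         eventsA$peak_sample < trials$end_sample[ti]] -
                     trials$start_sample[ti]) / fs * 1000
    relB[[ti]] <- (eventsB$peak_sample[eventsB$peak_sample >= trials$start_sample[ti] &
                                         eventsB$peak_sample < trials$end_sample[ti]] -
                     trials$start_sample[ti]) / fs * 1000
  }
  counts <- numeric(length(bins$centers))
  n_pairs <- 0
  for (ti in seq_len(nt)) {
    if (!length(relA[[ti]])) next
    acc <- numeric(length(bins$centers))
    for (tj in seq_len(nt)) {
      if (tj == ti || !length(relB[[tj]])) next
      d <- as.numeric(outer(relB[[tj]], relA[[ti]], "-"))
      acc <- acc + .hist_lags(d, bins)
      n_pairs <- n_pairs + length(d)
    }
    counts <- counts + acc / (nt - 1L)
  }
  .correlogram(bins$centers, counts, n_pairs, "shift_predictor")
}

#' Shift-predictor-normalized synchronization metric
#'
#' Sum of the true cross-correlogram in a +/- `window_ms` window divided by
#' the corresponding area of the chance (shift predictor) correlogram. A
#' value of 1 indicates synchrony at chance level; larger values indicate
#' above-chance coincidence. Invariant to rescaling both correlograms by a
#' common factor.
#'
#' @param true_ccg,predictor_ccg `correlogram`s on identical lag grids.
#' @param window_ms window half-width, ms.
#' @return scalar ratio.
#' @export
synchronization_metric <- function(true_ccg, predictor_ccg, window_ms = 50) {
  if (!isTRUE(all.equal(true_ccg$lags_ms, predictor_ccg$lags_ms)))
    stop("correlogram lag grids differ")
  sel <- abs(true_ccg$lags_ms) <= window_ms
  denom <- sum(predictor_ccg$counts[sel])
  if (denom <= 0) stop("zero predictor area in the synchronization window")
  sum(true_ccg$counts[sel]) / denom
}

#' Cross-scale coincidence with a circular-shift chance distribution
#'
#' Measures the coincidence of events detected at two spatial scales (e.g.
#' micro-array LFP ripples vs overlying iEEG ripples). The chance
#' correlogram is built by randomly circularly shifting the first event
#' train within each trial (`n_shift` times, averaged); the metric is the
#' mean true correlogram in a +/- `window_ms` window divided by the
#' corresponding chance area. 1 = chance.
#'
#' @param lfp_events,ieeg_events `ripple_events` tables.
#' @param trials a [trial_table()].
#' @param fs sampling rate, Hz.
#' @param max_lag_ms,bin_ms correlogram grid, ms.
#' @param window_ms coincidence window half-width, ms.
#' @param n_shift number of random shifts.
#' @param seed RNG seed.
#' @return list: `ratio`, `true` (`correlogram`), `chance` (mean chance
#'   counts), `n_shift`.
#' @export
circular_shift_coincidence <- function(lfp_events, ieeg_events, trials, fs,
                                       max_lag_ms = 200, bin_ms = 1,
                                       window_ms = 50, n_shift = 200,
                                       seed = 1L) {
  if (nrow(lfp_events) == 0L || nrow(ieeg_events) == 0L)
    stop("no events for coincidence analysis")
  truecc <- event_cross_correlogram(lfp_events, ieeg_events, trials, fs,
                                    max_lag_ms, bin_ms)
  set.seed(seed)
  bins <- .ccg_bins(max_lag_ms, bin_ms)
  chance <- numeric(length(bins$centers))
  for (s in seq_len(n_shift)) {
    shifted <- lfp_events
    for (ti in seq_len(nrow(trials))) {
      len <- trials$end_sample[ti] - trials$start_sample[ti]
      inb <- shifted$peak_sample >= trials$start_sample[ti] &
        shifted$peak_sample < trials$end_sample[ti]
      if (!any(inb)) next
      delta <- sample.int(len - 1L, 1L)
      shifted$peak_sample[inb] <- trials$start_sample[ti] +
        (shifted$peak_sample[inb] - trials$start_sample[ti] + delta) %% len
    }
    cc <- event_cross_correlogram(shifted, ieeg_events, trials, fs,
                                  max_lag_ms, bin_ms)
    chance <- chance + cc$counts
  }
  chance <- chance / n_shift
  sel <- abs(truecc$lags_ms) <= window_ms
  denom <- sum(chance[sel])
  if (denom <= 0) stop("zero chance area in the coincidence window")
  list(ratio = sum(truecc$counts[sel]) / denom, true = truecc,
       chance = chance, n_shift = n_shift)
}

#' Population spiking burst metric within ripples
#'
#' Sums spiking across all units, computes the auto-correlogram of the
#' population spike train within each detected macro-scale ripple, and
#' compares its mass in a +/- `window_ms` window around zero lag with the
#' auto-correlogram of random duration-matched windows placed between
#' ripples. A ratio above 1 indicates that in-ripple spiking is organized
#' into bursts beyond its between-ripple structure.
#'
#' @param trains list of [spike_train()].
#' @param ieeg_events `ripple_events` at the macro scale.
#' @param n total session samples.
#' @param fs sampling rate, Hz.
#' @param window_ms burst window half-width, ms.
#' @param max_lag_ms auto-correlogram extent, ms.
#' @param n_chance_per_event duration-matched chance windows drawn per
#'   event (averaged; reduces chance-estimate variance).
#' @param seed RNG seed for the matched-window placement.
#' @return list: `ratio`, `true_counts`, `chance_counts`, `lags_ms`,
#'   `n_in_ripple_spikes`.
#' @export
population_burst_metric <- function(trains, ieeg_events, n, fs,
                                    window_ms = 25, max_lag_ms = 50,
                                    n_chance_per_event = 5, seed = 1L) {
  if (nrow(ieeg_events) == 0L) stop("no ripple events")
  set.seed(seed)
  pop <- sort(unlist(lapply(trains, function(tr) tr$samples)))
  bins <- .ccg_bins(max_lag_ms, 1)
  acf_in_window <- function(lo, hi) {
    s <- pop[pop >= lo & pop <= hi]
    if (length(s) < 2L) return(list(counts = numeric(length(bins$centers)), k = length(s)))
    d <- outer(s, s, "-") / fs * 1000
    d <- d[row(d) != col(d)]
    list(counts = .hist_lags(as.numeric(d), bins), k = length(s))
  }
  # between-ripple free intervals
  occ <- ieeg_events[order(ieeg_events$start_sample), , drop = FALSE]
  free <- list(); cur <- 1L
  for (i in seq_len(nrow(occ))) {
    if (occ$start_sample[i] - 1L >= cur)
      free[[length(free) + 1L]] <- c(cur, occ$start_sample[i] - 1L)
    cur <- max(cur, occ$end_sample[i])
  }
  if (cur <= n) free[[length(free) + 1L]] <- c(cur, n)
  free <- do.call(rbind, free)
  true_c <- chance_c <- numeric(length(bins$centers))
  k_in <- 0L
  for (i in seq_len(nrow(ieeg_events))) {
    len <- ieeg_events$end_sample[i] - ieeg_events$start_sample[i]
    a <- acf_in_window(ieeg_events$start_sample[i], ieeg_events$end_sample[i] - 1L)
    true_c <- true_c + a$counts
    k_in <- k_in + a$k
    fit <- which(free[, 2L] - free[, 1L] + 1L >= len)
    if (!length(fit))
      stop("no between-ripple room for a duration-matched window")
    room <- free[fit, 2L] - free[fit, 1L] + 2L - len
    for (rep_i in seq_len(n_chance_per_event)) {
      pick <- fit[sample.int(length(fit), 1L, prob = room)]
      off <- sample.int(free[pick, 2L] - free[pick, 1L] + 2L - len, 1L) - 1L
      lo <- free[pick, 1L] + off
      chance_c <- chance_c + acf_in_window(lo, lo + len - 1L)$counts /
        n_chance_per_event
    }
  }
  sel <- abs(bins$centers) <= window_ms
  denom <- mean(chance_c[sel])
  num <- mean(true_c[sel])
  if (num == 0) return(list(ratio = 0, true_counts = true_c,
                            chance_counts = chance_c, lags_ms = bins$centers,
                            n_in_ripple_spikes = k_in))
  if (denom <= 0) stop("empty chance auto-correlogram")
  list(ratio = num / denom, true_counts = true_c,
       chance_counts = chance_c, lags_ms = bins$centers,
       n_in_ripple_spikes = k_in)
}

#' Windowed correlation between band amplitude and spike rate
#'
#' Averages a z-scored band-amplitude series and a z-scored spike-rate
#' series within non-overlapping windows (100 ms by default) and returns the
#' Pearson correlation across windows.
#'
#' @param amplitude_ts,rate_ts aligned numeric series.
#' @param fs sampling rate, Hz.
#' @param window_ms window length, ms.
#' @param sample_keep optional logical vector restricting which samples
#'   (e.g. retrieval-trial samples) enter the window means.
#' @return list: `r`, `n_windows`, `amp_means`, `rate_means`.
#' @export
windowed_amplitude_spike_correlation <- function(amplitude_ts, rate_ts, fs,
                                                 window_ms = 100,
                                                 sample_keep = NULL) {
  if (length(amplitude_ts) != length(rate_ts)) stop("series lengths differ")
  a <- zscore(amplitude_ts)
  r <- zscore(rate_ts)
  wlen <- max(1L, round(window_ms / 1000 * fs))
  nw <- length(a) %/% wlen
  if (nw < 3L) stop("need at least 3 windows")
  keep <- sample_keep %||% rep(TRUE, length(a))
  am <- rm_ <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    idx <- idx[keep[idx]]
    if (length(idx)) { am[w] <- mean(a[idx]); rm_[w] <- mean(r[idx]) }
  }
  ok <- is.finite(am) & is.finite(rm_)
  if (sum(ok) < 3L) stop("need at least 3 windows")
  list(r = stats::cor(am[ok], rm_[ok]), n_windows = sum(ok),
       amp_means = am, rate_means = rm_)
}

#' Permutation null from circular shifts of spike trains within trials
#'
#' Recomputes an arbitrary statistic after independently circularly
#' shifting every unit's spike indices within each trial (shift of 0 is
#' excluded from the draws), building a chance distribution that preserves
#' each train's within-trial structure while destroying its alignment to
#' everything else.
#'
#' @param stat_fn function(list of spike_train) -> scalar statistic.
#' @param trains list of [spike_train()].
#' @param trials a [trial_table()].
#' @param n_perm number of permutations (a warning is issued below 20).
#' @param seed RNG seed.
#' @param shared_shift use one shift per trial for all units?
#' @return list: `r_true`, `null` (vector), `null_mean`, `p` (one-sided
#'   exceedance, `(b + 1)/(n_perm + 1)` convention).
#' @export
circular_shift_correlation_null <- function(stat_fn, trains, trials,
                                            n_perm = 1000, seed = 1L,
                                            shared_shift = FALSE) {
  if (n_perm < 20L) warning("fewer than 20 permutations: p-values are coarse")
  r_true <- stat_fn(trains)
  set.seed(seed)
  lens <- trials$end_sample - trials$start_sample
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    deltas_shared <- vapply(lens, function(l) sample.int(l - 1L, 1L), integer(1))
    sh <- lapply(trains, function(tr) {
      s <- tr$samples
      for (ti in seq_len(nrow(trials))) {
        inb <- s >= trials$start_sample[ti] & s < trials$end_sample[ti]
        if (!any(inb)) next
        delta <- if (shared_shift) deltas_shared[ti] else
          sample.int(lens[ti] - 1L, 1L)
        s[inb] <- trials$start_sample[ti] +
          (s[inb] - trials$start_sample[ti] + delta) %% lens[ti]
      }
      tr$samples <- sort(unique(s))
      tr
    })
    null[b] <- stat_fn(sh)
  }
  list(r_true = r_true, null = null, null_mean = mean(null),
       p = (1 + sum(null >= r_true)) / (n_perm + 1))
}

#' Permutation null from circular shifts of a phase series within events
#'
#' Counterpart of [circular_shift_correlation_null()] for statistics of
#' band-limited phase: each channel's phase series is circularly shifted by
#' an independent random offset within every event before the statistic is
#' recomputed.
#'
#' @param stat_fn function(phase matrix) -> scalar statistic.
#' @param phase_mat channels x samples phase matrix.
#' @param events `ripple_events` defining the shift extents.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list: `r_true`, `null`, `null_mean`, `p`.
#' @export
circular_shift_phase_null <- function(stat_fn, phase_mat, events,
                                      n_perm = 100, seed = 1L) {
  r_true <- stat_fn(phase_mat)
  set.seed(seed)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- phase_mat
    for (i in seq_len(nrow(events))) {
      span <- events$start_sample[i]:(events$end_sample[i] - 1L)
      span <- span[span >= 1L & span <= ncol(pm)]
      len <- length(span)
      if (len < 2L) next
      for (ch in seq_len(nrow(pm))) {
        delta <- sample.int(len - 1L, 1L)
        pm[ch, span] <- pm[ch, span][((seq_len(len) - 1L + delta) %% len) + 1L]
      }
    }
    null[b] <- stat_fn(pm)
  }
  list(r_true = r_true, null = null, null_mean = mean(null),
       p = (1 + sum(null >= r_true)) / (n_perm + 1))
}

#' Fisher's z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, variance-stabilizing for averaging correlations.
#'
#' @param r correlation(s), `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}
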