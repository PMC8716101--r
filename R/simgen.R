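# Synthetic multi-scale session generator.
#
# Emulates the statistical structure the analysis chain assumes: 1/f
# background with 60/120 Hz mains components, transient 80-120 Hz ripple
# bursts spanning a continuum of amplitudes and durations, a 96-channel
# micro-array whose ripple events are partly shared (time- and phase-aligned)
# across channels, overlying macro-scale iEEG channels formed from the array
# ensemble plus independent noise, trough-locked spiking, sharp interictal
# discharge (IED) transients, and a trial structure with higher ripple rates
# on correct trials. Every injected event is recorded as ground truth.

# Rayleigh envelope constants for a Gaussian band-limited signal:
# mean = sigma*sqrt(pi/2), sd = sigma*sqrt(2 - pi/2).
.RAYLEIGH_MEAN <- sqrt(pi / 2)
.RAYLEIGH_SD <- sqrt(2 - pi / 2)

#' Configuration of a synthetic multi-scale session
#'
#' Defaults are the package's reference study conditions: a 600 s session of
#' 150 four-second trials at 1000 Hz, a 96-channel micro-array under 4 iEEG
#' channels, per-channel ripple rates of 0.45 Hz (correct trials) and 0.30 Hz
#' (incorrect), which with a 35% correct rate gives a session-mean ripple
#' rate of about 0.35 Hz, a log-normal amplitude continuum (median 2.5
#' envelope-SD, sigma_log 0.4) and a gamma duration continuum (shape 3, mean
#' 40 ms, floor 15 ms).
#'
#' Event amplitude is specified in envelope-SD units: the expected peak of
#' the 80-120 Hz Hilbert envelope, expressed as a z-score of the session
#' envelope. Event duration is specified as the expected time the envelope
#' spends above the 2-SD detection extent threshold (for events too weak to
#' reach it, the Hann window is capped at five nominal durations).
#'
#' @param sampling_rate sampling rate, Hz.
#' @param n_mea_channels number of micro-array (LFP) channels.
#' @param n_ieeg_channels number of overlying iEEG channels.
#' @param session_duration session length, s.
#' @param trial_duration trial length, s.
#' @param trial_count number of trials (trials tile the session start).
#' @param prop_correct probability that a trial is labelled correct.
#' @param noise_exponent 1/f spectral slope of the background (PSD ~ f^-a).
#' @param channel_sd per-channel background standard deviation (arbitrary
#'   voltage units).
#' @param line_noise_amp amplitude of the 60 and 120 Hz mains sinusoids.
#' @param ripple_rate_correct,ripple_rate_incorrect per-channel ripple rates
#'   (Hz) on correct / incorrect trials.
#' @param ripple_freq_range ripple band, Hz.
#' @param ripple_amp_dist list(meanlog, sdlog): log-normal amplitude
#'   distribution in envelope-SD units.
#' @param ripple_dur_dist list(shape, mean_ms, floor_ms): gamma duration
#'   distribution.
#' @param cross_channel_alignment fraction of events shared (same time and
#'   phase) across all MEA channels, between 0 and 1.
#' @param ieeg_mixing_weight weight of the MEA ensemble mean in each iEEG
#'   channel (0 = iEEG independent of the array).
#' @param spike_baseline_rate baseline Poisson firing rate per unit, Hz.
#' @param spike_burst_rate in-ripple extra firing rate per unit at the median
#'   event amplitude, Hz (scales linearly with event amplitude).
#' @param spike_lock_phase preferred ripple phase of in-event spikes; pi is
#'   the trough under the `x = A*cos(phi)` convention.
#' @param locking_kappa von Mises concentration of in-event spike phases.
#' @param ied_rate rate of interictal-discharge transients, Hz.
#' @param ied_amp_sd IED peak amplitude in units of channel SD (>= 8 so the
#'   z > 5 artifact rule fires).
#' @param waveform_peak,waveform_trough,waveform_noise_sd synthetic spike
#'   waveform parameters (arbitrary units).
#' @param seed master seed; every sub-generator derives its own stream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 1000,
                       n_mea_channels = 96,
                       n_ieeg_channels = 4,
                       session_duration = 600,
                       trial_duration = 4,
                       trial_count = NULL,
                       prop_correct = 0.35,
                       noise_exponent = 2,
                       channel_sd = 1,
                       line_noise_amp = 0.5,
                       ripple_rate_correct = 0.45,
                       ripple_rate_incorrect = 0.30,
                       ripple_freq_range = c(80, 120),
                       ripple_amp_dist = list(meanlog = log(2.5), sdlog = 0.4),
                       ripple_dur_dist = list(shape = 3, mean_ms = 40, floor_ms = 15),
                       cross_channel_alignment = 0.4,
                       ieeg_mixing_weight = 1,
                       spike_baseline_rate = 2.5,
                       spike_burst_rate = 25,
                       spike_lock_phase = pi,
                       locking_kappa = 5,
                       ied_rate = 0.05,
                       ied_amp_sd = 10,
                       waveform_peak = 30,
                       waveform_trough = -80,
                       waveform_noise_sd = 8,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$trial_count))
    cfg$trial_count <- floor(session_duration / trial_duration)
  with(cfg, {
    if (sampling_rate <= 0 || session_duration <= 0)
      stop("sampling rate and session duration must be positive")
    if (any(c(ripple_rate_correct, ripple_rate_incorrect, spike_baseline_rate,
              spike_burst_rate, ied_rate) < 0))
      stop("all rates must be >= 0")
    if (cross_channel_alignment < 0 || cross_channel_alignment > 1)
      stop("cross_channel_alignment must be in [0, 1]")
    if (ripple_freq_range[1] <= 0 || ripple_freq_range[2] >= sampling_rate / 2 ||
        ripple_freq_range[1] >= ripple_freq_range[2])
      stop("ripple_freq_range must lie within (0, Nyquist)")
    if (locking_kappa < 0) stop("locking_kappa must be >= 0")
    if (trial_count * trial_duration > session_duration + 1e-9)
      stop("trials do not fit in the session")
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %g s @ %g Hz, %d MEA + %d iEEG channels, ",
                     "%d trials, ripple rates %.2f/%.2f Hz, alignment %.2f, ",
                     "kappa %.1f, seed %d\n"),
              x$session_duration, x$sampling_rate, x$n_mea_channels,
              x$n_ieeg_channels, x$trial_count, x$ripple_rate_correct,
              x$ripple_rate_incorrect, x$cross_channel_alignment,
              x$locking_kappa, as.integer(x$seed)))
  invisible(x)
}

# 1/f-shaped Gaussian noise, one channel, via frequency-domain shaping of
# white noise; variance rescaled exactly to sd^2. PSD ~ f^-exponent above
# 1 Hz, flat below (avoids the DC divergence).
.one_over_f <- function(n, fs, exponent, sd) {
  x <- stats::rnorm(n)
  if (exponent != 0) {
    freq <- abs(seq(0, fs, length.out = n + 1L)[-(n + 1L)])
    freq[freq > fs / 2] <- fs - freq[freq > fs / 2]
    shape <- pmax(freq, 1)^(-exponent / 2)
    shape[1L] <- 0
    x <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  }
  s <- stats::sd(x)
  if (s > 0) x <- x / s * sd
  x
}

#' Generate background recordings (1/f noise plus mains components)
#'
#' Channels are independent. With `noise_exponent = 0` and
#' `line_noise_amp = 0` the output is white noise at the configured variance.
#'
#' @param config a [sim_config()].
#' @param n_channels number of channels to generate (defaults to
#'   `config$n_mea_channels`).
#' @param scale `"LFP"` or `"iEEG"` tag for the output.
#' @param seed RNG stream seed (defaults to a stream derived from
#'   `config$seed`).
#' @return a [ts_recording()].
#' @export
gen_background <- function(config, n_channels = config$n_mea_channels,
                           scale = "LFP",
                           seed = sub_seed(config$seed, paste0("bg", scale))) {
  fs <- config$sampling_rate
  n <- round(config$session_duration * fs)
  if (n <= 0) stop("non-positive session length")
  set.seed(seed)
  dat <- matrix(0, n_channels, n)
  t <- seq_len(n) / fs
  for (ch in seq_len(n_channels)) {
    x <- .one_over_f(n, fs, config$noise_exponent, config$channel_sd)
    if (config$line_noise_amp > 0) {
      for (f0 in c(60, 120))
        x <- x + config$line_noise_amp * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
    }
    dat[ch, ] <- x
  }
  ts_recording(dat, fs, scale = scale)
}

# Envelope calibration: measured ripple-band SD of one background channel ->
# Rayleigh-theory envelope mean and SD used to convert amplitude z-units into
# additive burst amplitudes.
.envelope_stats <- function(ts, band) {
  x <- band_filter_hilbert(ts$data[1L, ], ts$fs, band)
  sb <- stats::sd(Mod(x$analytic))
  mb <- mean(Mod(x$analytic))
  list(mean = mb, sd = sb)
}

# Fraction of a Hann window sin^2(pi t / W) spent above level c in (0, 1).
.hann_frac_above <- function(c) {
  c <- pmin(pmax(c, 0), 1)
  1 - (2 / pi) * asin(sqrt(c))
}

# Zero-phase (forward-backward) magnitude gain of the detection band-pass
# at frequency f: |H(f)|^2 of the order-2 Butterworth design.
.bandpass_gain <- function(fs, band, f) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  H <- as.vector(z %*% bf$b) / as.vector(z %*% bf$a)
  Mod(H)^2
}

# Draw per-event parameters; returns a data.frame without times.
# The additive burst amplitude is compensated for the band-pass attenuation
# at the carrier frequency, because amplitudes are specified as the peak of
# the *filtered* ripple-band envelope.
.draw_event_params <- function(k, config, env) {
  A <- stats::rlnorm(k, config$ripple_amp_dist$meanlog, config$ripple_amp_dist$sdlog)
  d <- config$ripple_dur_dist
  D <- pmax(stats::rgamma(k, shape = d$shape, scale = d$mean_ms / d$shape), d$floor_ms)
  f <- stats::runif(k, config$ripple_freq_range[1], config$ripple_freq_range[2])
  phi <- stats::runif(k, -pi, pi)
  # additive burst amplitude: expected filtered-envelope peak z = A
  gain <- .bandpass_gain(config$sampling_rate, config$ripple_freq_range, f)
  B <- (env$mean + A * env$sd) / pmax(gain, 0.25)
  # Hann window length so that expected time above the 2-SD extent threshold
  # equals the nominal duration; capped for sub-threshold events
  c_lvl <- (env$mean + 2 * env$sd) / B
  frac <- pmax(.hann_frac_above(c_lvl), 0.2)
  data.frame(amplitude = A, duration_ms = D, center_freq = f, phase = phi,
             burst_amp = B, window_ms = D / frac)
}

#' Inject transient ripple bursts into a recording
#'
#' Adds Hann-windowed sinusoidal bursts with per-event center frequency drawn
#' in the ripple band and amplitude/duration drawn from the configured
#' continuum. Event times follow a Poisson process whose rate depends on the
#' trial label when a trial table is supplied. A fraction
#' `cross_channel_alignment` of events is shared — identical time, frequency,
#' phase and amplitude — across all channels; the rest are channel-private.
#' Events whose window would leave the session, or overlap an earlier event
#' on the same channel, are resampled and eventually dropped (with a
#' message).
#'
#' @param ts background [ts_recording()] from [gen_background()].
#' @param config a [sim_config()].
#' @param trials optional [trial_table()]; when `NULL` a homogeneous process
#'   at `ripple_rate_correct` covers the whole session.
#' @param seed RNG stream seed.
#' @return list with elements `ts` (recording with bursts added) and `truth`
#'   (data.frame: channel, start/end/center sample, window span, center
#'   frequency, amplitude in envelope-SD units, nominal duration, shared
#'   flag).
#' @export
inject_ripples <- function(ts, config, trials = NULL,
                           seed = sub_seed(config$seed, "ripples")) {
  fs <- ts$fs
  n <- n_samples(ts)
  nch <- n_channels(ts)
  band <- config$ripple_freq_range
  # Amplitudes are specified as z-scores of the *session* envelope, whose
  # statistics include the events themselves. Calibrate by injecting a
  # provisional event stream into a probe copy of channel 1 and measuring
  # the resulting envelope mean/SD, iterating the fixed point to
  # convergence (the events inflate the very statistics that define their
  # units).
  env <- .envelope_stats(ts, band)
  set.seed(sub_seed(seed, "calibration"))
  rate_mean <- if (is.null(trials)) config$ripple_rate_correct else
    config$prop_correct * config$ripple_rate_correct +
      (1 - config$prop_correct) * config$ripple_rate_incorrect
  for (iter in 1:12) {
    env_prev <- env
    probe <- ts$data[1L, ]
    k <- stats::rpois(1L, rate_mean * n / fs)
    if (k > 0L) {
      par <- .draw_event_params(k, config, env)
      cs <- round(stats::runif(k, 0, n / fs) * fs) + 1L
      for (j in seq_len(k)) {
        W <- round(par$window_ms[j] / 1000 * fs)
        s0 <- cs[j] - W %/% 2L; s1 <- s0 + W - 1L
        if (s0 < 1L || s1 > n) next
        idx <- s0:s1
        probe[idx] <- probe[idx] + par$burst_amp[j] *
          sin(pi * (idx - s0) / (s1 - s0))^2 *
          cos(2 * pi * par$center_freq[j] * (idx - cs[j]) / fs + par$phase[j])
      }
    }
    a <- band_filter_hilbert(probe, fs, band)$amplitude
    env <- list(mean = mean(a), sd = stats::sd(a))
    if (abs(env$sd - env_prev$sd) < 0.02 * env_prev$sd && iter >= 2L) break
  }
  set.seed(seed)

  # candidate event center times (seconds): Poisson with the label-dependent
  # per-channel rate, scaled by `mult` (the shared / private stream fraction)
  draw_times <- function(mult) {
    if (is.null(trials)) {
      k <- stats::rpois(1L, mult * config$ripple_rate_correct * n / fs)
      return(sort(stats::runif(k, 0, n / fs)))
    }
    out <- numeric(0)
    for (i in seq_len(nrow(trials))) {
      lab_rate <- if (trials$label[i] == "correct")
        config$ripple_rate_correct else config$ripple_rate_incorrect
      dur <- (trials$end_sample[i] - trials$start_sample[i]) / fs
      k <- stats::rpois(1L, mult * lab_rate * dur)
      out <- c(out, (trials$start_sample[i] - 1L) / fs + stats::runif(k, 0, dur))
    }
    sort(out)
  }

  shared_t <- draw_times(config$cross_channel_alignment)
  shared_par <- .draw_event_params(length(shared_t), config, env)

  truth <- list()
  dat <- ts$data
  occupied <- vector("list", nch)   # per-channel matrix of window spans

  place <- function(ch, t_center, par, shared_flag) {
    W <- round(par$window_ms / 1000 * fs)
    cs <- round(t_center * fs) + 1L
    s0 <- cs - W %/% 2L
    s1 <- s0 + W - 1L
    if (s0 < 1L || s1 > n) return(NULL)
    occ <- occupied[[ch]]
    if (!is.null(occ) && nrow(occ) &&
        any(occ[, 1L] <= s1 & occ[, 2L] >= s0)) return(NULL)
    occupied[[ch]] <<- rbind(occ, c(s0, s1))
    idx <- s0:s1
    h <- sin(pi * (idx - s0) / (s1 - s0))^2
    dat[ch, idx] <<- dat[ch, idx] +
      par$burst_amp * h * cos(2 * pi * par$center_freq * (idx - cs) / fs + par$phase)
    half_core <- round(par$duration_ms / 2000 * fs)
    data.frame(channel = ch, start_sample = max(1L, cs - half_core),
               end_sample = min(n, cs + half_core), center_sample = cs,
               window_start = s0, window_end = s1,
               center_freq = par$center_freq, amplitude = par$amplitude,
               duration_ms = par$duration_ms, phase = par$phase,
               shared = shared_flag)
  }

  n_dropped <- 0L
  for (j in seq_along(shared_t)) {
    rows <- lapply(seq_len(nch), function(ch)
      place(ch, shared_t[j], shared_par[j, ], TRUE))
    ok <- !vapply(rows, is.null, logical(1))
    if (!all(ok)) n_dropped <- n_dropped + sum(!ok)
    truth <- c(truth, rows[ok])
  }
  for (ch in seq_len(nch)) {
    tt <- draw_times(1 - config$cross_channel_alignment)
    par <- .draw_event_params(length(tt), config, env)
    for (j in seq_along(tt)) {
      row <- place(ch, tt[j], par[j, ], FALSE)
      tries <- 0L
      while (is.null(row) && tries < 20L) {
        tries <- tries + 1L
        t_new <- if (is.null(trials)) stats::runif(1, 0, n / fs) else
          stats::runif(1, (trials$start_sample[1] - 1) / fs,
                       trials$end_sample[nrow(trials)] / fs)
        row <- place(ch, t_new, par[j, ], FALSE)
      }
      if (is.null(row)) n_dropped <- n_dropped + 1L else
        truth <- c(truth, list(row))
    }
  }
  if (n_dropped > 0L)
    message(sprintf("inject_ripples: dropped %d event placements (overlap or bounds)",
                    n_dropped))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel = integer(), start_sample = integer(),
               end_sample = integer(), center_sample = integer(),
               window_start = integer(), window_end = integer(),
               center_freq = numeric(), amplitude = numeric(),
               duration_ms = numeric(), phase = numeric(), shared = logical())
  truth <- truth[order(truth$channel, truth$start_sample), , drop = FALSE]
  rownames(truth) <- NULL
  out <- ts
  out$data <- dat
  list(ts = out, truth = truth)
}

# 32-sample biphasic waveform template.
.wf_template <- function(peak, trough) {
  i <- 1:32
  peak * exp(-((i - 8) / 2.2)^2) + trough * exp(-((i - 14) / 2.8)^2) -
    0.25 * trough * exp(-((i - 22) / 4)^2)
}

#' Generate ripple-locked spike trains
#'
#' One unit per channel present in the ground-truth table. Each unit fires
#' baseline Poisson spikes across the session plus, within each ripple event
#' on its channel, burst spikes whose ripple-band phase is von Mises
#' distributed around `spike_lock_phase` (the trough, by default) with
#' concentration `locking_kappa`. The in-event burst rate scales linearly
#' with event amplitude, so stronger ripples carry more spikes. Synthetic
#' 32-sample waveforms with configurable peak, trough and residual SD are
#' attached to every spike.
#'
#' @param truth ground-truth event table from [inject_ripples()].
#' @param config a [sim_config()].
#' @param n total number of session samples.
#' @param channels channels to generate units for (default: all channels in
#'   `truth`; must be non-empty).
#' @param seed RNG stream seed.
#' @return list of [spike_train()] objects.
#' @export
gen_locked_spikes <- function(truth, config, n,
                              channels = sort(unique(truth$channel)),
                              seed = sub_seed(config$seed, "spikes")) {
  if (config$locking_kappa < 0) stop("locking_kappa must be >= 0")
  set.seed(seed)
  fs <- config$sampling_rate
  med_amp <- exp(config$ripple_amp_dist$meanlog)
  template <- .wf_template(config$waveform_peak, config$waveform_trough)
  trains <- vector("list", length(channels))
  for (ui in seq_along(channels)) {
    ch <- channels[ui]
    k_base <- stats::rpois(1L, config$spike_baseline_rate * n / fs)
    s_base <- sort(sample.int(n, min(k_base, n)))
    ev <- truth[truth$channel == ch, , drop = FALSE]
    s_burst <- integer(0)
    if (nrow(ev) && config$spike_burst_rate > 0) {
      for (j in seq_len(nrow(ev))) {
        dur_s <- (ev$end_sample[j] - ev$start_sample[j]) / fs
        kb <- stats::rpois(1L, config$spike_burst_rate * dur_s *
                             ev$amplitude[j] / med_amp)
        if (kb == 0L) next
        psi <- rvonmises(kb, config$spike_lock_phase, config$locking_kappa)
        f <- ev$center_freq[j]
        # map phases to sample times: Phi(t) = 2*pi*f*(t - t_c) + phi0
        base <- (psi - ev$phase[j]) / (2 * pi * f)
        span0 <- (ev$start_sample[j] - ev$center_sample[j]) / fs
        span1 <- (ev$end_sample[j] - ev$center_sample[j]) / fs
        k_lo <- ceiling((span0 - base) * f)
        k_hi <- floor((span1 - base) * f)
        ok <- k_hi >= k_lo
        if (!any(ok)) next
        cyc <- k_lo[ok] + floor(stats::runif(sum(ok)) * (k_hi[ok] - k_lo[ok] + 1))
        tt <- base[ok] + cyc / f
        s_burst <- c(s_burst, ev$center_sample[j] + round(tt * fs))
      }
    }
    samples <- sort(unique(c(s_base, s_burst)))
    samples <- samples[samples >= 1L & samples <= n]
    wf <- matrix(rep(template, each = length(samples)), nrow = length(samples)) +
      matrix(stats::rnorm(length(samples) * 32L, 0, config$waveform_noise_sd),
             ncol = 32L)
    trains[[ui]] <- spike_train(unit = paste0("u", ch), samples = samples,
                                fs = fs, channel = ch, waveforms = wf)
  }
  trains
}

#' Build a complete synthetic session
#'
#' Assembles trials, micro-array LFP with injected ripples, overlying iEEG
#' channels (weighted MEA ensemble mean plus independent 1/f noise), shared
#' IED transients at both scales, ripple-locked spike trains and the full
#' ground truth. Identical config and seed give a bit-identical session.
#'
#' @param config a [sim_config()].
#' @return an object of class `ripple_session`: list with `ieeg`, `lfp`
#'   ([ts_recording()]), `spikes` (list of [spike_train()]), `trials`
#'   ([trial_table()]), `truth` (list: `ripples`, `ieeg_ripples`,
#'   `ied_samples`, `spike_lock_phase`, `spike_counts`) and `config`.
#' @export
build_session <- function(config) {
  fs <- config$sampling_rate
  n <- round(config$session_duration * fs)

  set.seed(sub_seed(config$seed, "trials"))
  len <- round(config$trial_duration * fs)
  starts <- seq(1L, by = len, length.out = config$trial_count)
  labels <- ifelse(stats::runif(config$trial_count) < config$prop_correct,
                   "correct", "incorrect")
  trials <- trial_table(starts, starts + len, starts + round(0.75 * len), labels)

  lfp_bg <- gen_background(config, config$n_mea_channels, "LFP")
  inj <- inject_ripples(lfp_bg, config, trials)
  lfp <- inj$ts
  truth <- inj$truth

  ieeg_bg <- gen_background(config, config$n_ieeg_channels, "iEEG")
  mea_mean <- colMeans(lfp$data)
  ieeg <- ieeg_bg
  ieeg$data <- ieeg_bg$data +
    matrix(rep(config$ieeg_mixing_weight * mea_mean, each = config$n_ieeg_channels),
           nrow = config$n_ieeg_channels)

  # IED transients: stereotyped biphasic sharp wave (~50 ms), shared times
  set.seed(sub_seed(config$seed, "ied"))
  ied_samples <- integer(0)
  if (config$ied_rate > 0) {
    k <- stats::rpois(1L, config$ied_rate * n / fs)
    if (k > 0L) {
      half <- round(0.025 * fs)
      tmpl_t <- (-half:half) / fs
      tmpl <- -tmpl_t / 0.008 * exp(0.5 - (tmpl_t / 0.008)^2 / 2)  # biphasic
      tmpl <- tmpl / max(abs(tmpl)) * config$ied_amp_sd * config$channel_sd
      centers <- sort(sample.int(n - 2L * half, k) + half)
      for (cs in centers) {
        idx <- (cs - half):(cs + half)
        lfp$data[, idx] <- sweep(lfp$data[, idx, drop = FALSE], 2L, tmpl, "+")
        ieeg$data[, idx] <- sweep(ieeg$data[, idx, drop = FALSE], 2L, tmpl, "+")
      }
      ied_samples <- centers
    }
  }

  spikes <- gen_locked_spikes(truth, config, n,
                              channels = seq_len(config$n_mea_channels))

  shared <- truth[truth$shared & truth$channel == truth$channel[1L], , drop = FALSE]
  if (nrow(truth) == 0L) shared <- truth
  structure(list(
    ieeg = ieeg, lfp = lfp, spikes = spikes, trials = trials,
    truth = list(ripples = truth,
                 ieeg_ripples = shared,
                 ied_samples = ied_samples,
                 spike_lock_phase = config$spike_lock_phase,
                 spike_counts = vapply(spikes, function(s) length(s$samples),
                                       integer(1))),
    config = config), class = "ripple_session")
}

#' @export
print.ripple_session <- function(x, ...) {
  cat(sprintf(paste0("<ripple_session> %.0f s @ %g Hz | %d LFP + %d iEEG channels | ",
                     "%d truth ripples (%d shared) | %d units | %d trials\n"),
              n_samples(x$lfp) / x$lfp$fs, x$lfp$fs, n_channels(x$lfp),
              n_channels(x$ieeg), nrow(x$truth$ripples),
              sum(x$truth$ripples$shared), length(x$spikes), nrow(x$trials)))
  invisible(x)
}
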