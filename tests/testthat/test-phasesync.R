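# PPC estimator, Rayleigh test, spike-field spectra, shuffle z-scoring,
# condition contrasts, ripple-alignment PPC, spike-triggered averages.

fs <- 1000

test_that("PPC: analytic cases, double-loop equivalence, invariances", {
  expect_equal(ppc(rep(1.3, 7))$ppc, 1, tolerance = 1e-12)
  expect_equal(ppc(c(0, pi))$ppc, -1, tolerance = 1e-12)
  expect_equal(ppc(c(0, pi / 2, pi, 3 * pi / 2))$ppc, -1 / 3, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:25) {
    th <- runif(sample(2:200, 1), -pi, pi)
    expect_equal(ppc(th)$ppc, ppc_double_loop(th), tolerance = 1e-12)
    # rotation invariance and range
    expect_equal(ppc(th + 0.83)$ppc, ppc(th)$ppc, tolerance = 1e-10)
    expect_gte(ppc(th)$ppc, -1 / (length(th) - 1) - 1e-12)
    expect_lte(ppc(th)$ppc, 1 + 1e-12)
  }
  expect_error(ppc(0.5), "2 phases")
})

test_that("APCD matches a direct mod-pi pair average", {
  set.seed(32)
  th <- runif(40, -pi, pi)
  N <- length(th)
  acc <- 0
  for (j in 1:(N - 1)) for (k in (j + 1):N)
    acc <- acc + (abs(th[j] - th[k]) %% pi)
  expect_equal(ppc(th)$apcd, 2 * acc / (N * (N - 1)), tolerance = 1e-12)
})

test_that("Rayleigh test: concentration, calibration, power", {
  expect_lt(rayleigh_test(rep(0.2, 100))$p, 1e-10)

  set.seed(33)
  ps <- replicate(2000, rayleigh_test(runif(40, -pi, pi))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  rej <- mean(replicate(400, rayleigh_test(rvonmises(50, 0, 2))$p < 0.001))
  expect_gt(rej, 0.95)

  expect_error(rayleigh_test(1), "2 phases")
})

test_that("spike-field PPC spectrum peaks at the locked ripple frequency", {
  cfg <- sim_config(session_duration = 90, n_mea_channels = 4,
                    cross_channel_alignment = 0, locking_kappa = 5,
                    spike_baseline_rate = 0.5, spike_burst_rate = 80,
                    ripple_amp_dist = list(meanlog = log(10), sdlog = 0.2),
                    ripple_dur_dist = list(shape = 3, mean_ms = 60, floor_ms = 30),
                    ied_rate = 0, seed = 34L)
  ses <- suppressMessages(build_session(cfg))
  freqs <- exp(seq(log(2), log(400), length.out = 30))
  sp <- suppressMessages(spike_field_ppc_spectrum(ses$spikes, ses$lfp,
                                                  ses$trials, freqs))
  # burst clustering also locks spikes to slow fluctuations, so the peak is
  # sought above 30 Hz where the ripple-band effect lives
  hi <- sp$freqs > 30
  pk <- sp$freqs[hi][which.max(sp$spectrum[hi])]
  grid_step <- exp(diff(log(range(freqs))) / 29)
  expect_lt(abs(log(pk / 100)), 1.5 * log(grid_step))

  # kappa doubling increases PPC at the locked frequency (matched seeds)
  cfg2 <- cfg; cfg2$locking_kappa <- 10
  ses2 <- suppressMessages(build_session(cfg2))
  sp2 <- suppressMessages(spike_field_ppc_spectrum(ses2$spikes, ses2$lfp,
                                                   ses2$trials, freqs))
  i100 <- which.min(abs(freqs - 100))
  expect_gt(sp2$spectrum[i100], sp$spectrum[i100])
})

test_that("trial-shuffle z-scoring separates locked from unlocked spiking", {
  freqs <- exp(seq(log(4), log(300), length.out = 16))
  mk <- function(kappa, seed) {
    cfg <- sim_config(session_duration = 40, n_mea_channels = 2,
                      cross_channel_alignment = 0, locking_kappa = kappa,
                      spike_baseline_rate = 2, spike_burst_rate = 60,
                      ripple_amp_dist = list(meanlog = log(10), sdlog = 0.2),
                      ripple_dur_dist = list(shape = 3, mean_ms = 60, floor_ms = 30),
                      ied_rate = 0, seed = seed)
    suppressMessages(build_session(cfg))
  }
  ses <- mk(6, 35L)
  z <- suppressMessages(zscore_ppc_by_trial_shuffle(
    ses$spikes, ses$lfp, ses$trials, freqs, n_shuffle = 40, seed = 7L))
  i100 <- which.min(abs(freqs - 100))
  expect_gt(z$z[i100], 3)

  # unlocked: z-scores mostly within the null range
  ses0 <- mk(0, 36L)
  z0 <- suppressMessages(zscore_ppc_by_trial_shuffle(
    ses0$spikes, ses0$lfp, ses0$trials, freqs, n_shuffle = 40, seed = 7L))
  expect_gte(mean(abs(z0$z) < 3), 0.85)

  # fixed seed reproducible bit-exactly
  z0b <- suppressMessages(zscore_ppc_by_trial_shuffle(
    ses0$spikes, ses0$lfp, ses0$trials, freqs, n_shuffle = 40, seed = 7L))
  expect_identical(z0$z, z0b$z)
})

test_that("condition contrast: identical conditions give zero delta, locking is detected", {
  cfg <- sim_config(session_duration = 40, n_mea_channels = 2,
                    cross_channel_alignment = 0, locking_kappa = 6,
                    spike_baseline_rate = 3, spike_burst_rate = 60,
                    ripple_amp_dist = list(meanlog = log(10), sdlog = 0.2),
                    ripple_dur_dist = list(shape = 3, mean_ms = 60, floor_ms = 30),
                    ied_rate = 0, seed = 37L)
  ses <- suppressMessages(build_session(cfg))
  freqs <- exp(seq(log(4), log(300), length.out = 16))
  inside <- lapply(ses$spikes, function(tr) {
    ev <- ses$truth$ripples[ses$truth$ripples$channel == tr$channel, ]
    keep <- rep(FALSE, length(tr$samples))
    for (i in seq_len(nrow(ev)))
      keep <- keep | (tr$samples >= ev$start_sample[i] &
                        tr$samples <= ev$end_sample[i])
    tr$samples[keep]
  })
  outside <- lapply(seq_along(ses$spikes), function(ui)
    setdiff(ses$spikes[[ui]]$samples, inside[[ui]]))

  # identical conditions: delta identically zero (no subsampling path)
  same <- compare_ppc_conditions(ses$spikes, ses$lfp, inside, inside,
                                 freqs = freqs, n_subsample = 20)
  expect_true(all(abs(same$mean_delta) < 1e-12))

  cmp <- compare_ppc_conditions(ses$spikes, ses$lfp, inside, outside,
                                freqs = freqs, n_subsample = 50, seed = 3L)
  i100 <- which.min(abs(freqs - 100))
  expect_gt(cmp$mean_delta[i100], 0.05)

  # min-spike exclusion
  few <- lapply(inside, function(s) s[seq_len(min(3, length(s)))])
  expect_error(compare_ppc_conditions(ses$spikes, ses$lfp, few, few,
                                      freqs = freqs, min_spikes = 10),
               "minimum spike")
})

test_that("ripple-alignment PPC: identical channels give 1, aligned beats unaligned", {
  # identical phases across channels
  ph <- matrix(rep(runif(500, -pi, pi), each = 8), nrow = 8)
  ev <- data.frame(channel = 1L, start_sample = 100L, end_sample = 200L,
                   peak_sample = 150L, peak_z = 4, duration_ms = 100,
                   band_lo = 80, band_hi = 120)
  out <- ripple_alignment_ppc(ev, ph)
  expect_equal(out$max_ppc, 1, tolerance = 1e-12)

  # iid uniform phases: max over event samples matches a direct simulation
  set.seed(38)
  phu <- matrix(runif(8 * 2000, -pi, pi), nrow = 8)
  evu <- data.frame(channel = 1L, start_sample = seq(1, 1901, by = 100),
                    end_sample = seq(51, 1951, by = 100))
  outu <- ripple_alignment_ppc(evu, phu)
  null_max <- replicate(400, max(vapply(1:50, function(i)
    rippletools:::.ppc_val(runif(8, -pi, pi)), numeric(1))))
  expect_gt(ks.test(outu$max_ppc, null_max)$p.value, 0.01)

  # generator: alignment 1 vs 0 on matched seeds
  val <- function(a, seed) {
    cfg <- sim_config(session_duration = 40, n_mea_channels = 8,
                      n_ieeg_channels = 1, cross_channel_alignment = a,
                      ied_rate = 0, seed = seed)
    ses <- suppressMessages(build_session(cfg))
    evi <- detect_ripples(ses$ieeg, detection_params(preset = "relaxed"))
    bh <- band_filter_hilbert(ses$lfp, band = c(80, 120))
    mean(ripple_alignment_ppc(evi, bh$phase)$max_ppc, na.rm = TRUE)
  }
  expect_gt(val(1, 39L), val(0, 39L))

  expect_error(ripple_alignment_ppc(ev, ph[1, , drop = FALSE]), "2 micro")
})

test_that("restricting alignment PPC to rippling channels changes the channel sets", {
  set.seed(40)
  ph <- matrix(runif(6 * 1000, -pi, pi), nrow = 6)
  ev <- data.frame(channel = 1L, start_sample = 200L, end_sample = 300L)
  lfp_ev <- data.frame(channel = c(2L, 5L), start_sample = c(180L, 240L),
                       end_sample = c(260L, 320L))
  out <- ripple_alignment_ppc(ev, ph, lfp_events = lfp_ev)
  expect_equal(out$n_channels, 2L)
  lfp_ev1 <- lfp_ev[1, ]
  out1 <- ripple_alignment_ppc(ev, ph, lfp_events = lfp_ev1)
  expect_true(is.na(out1$max_ppc))  # < 2 concurrent channels
})

test_that("spike-triggered average finds troughs and respects restriction", {
  t <- seq_len(20 * fs) / fs
  x <- cos(2 * pi * 5 * t)
  troughs <- which(abs(x + 1) < 1e-9)
  tr <- spike_train("u", troughs, fs)
  sta <- spike_triggered_average(tr, x, fs, window_ms = 150)
  expect_equal(sta$lag_s[which.min(sta$sta)], 0)

  # random spikes on noise: amplitude shrinks ~ 1/sqrt(n)
  set.seed(41)
  noise <- rnorm(20 * fs)
  amp_n <- function(k) {
    trn <- spike_train("u", sort(sample(200:(20 * fs - 200), k)), fs)
    max(abs(spike_triggered_average(trn, noise, fs, 100)$sta))
  }
  a1 <- mean(replicate(10, amp_n(50)))
  a2 <- mean(replicate(10, amp_n(800)))
  expect_lt(a2, a1 / 2)

  # restriction bookkeeping is exact
  ev <- data.frame(channel = 1, start_sample = 5000L, end_sample = 7000L)
  trs <- spike_train("u", c(4000L, 5500L, 6500L, 9000L), fs)
  expect_equal(spike_triggered_average(trs, noise, fs, 50, events = ev,
                                       restrict = "inside")$n_spikes, 2L)
  expect_equal(spike_triggered_average(trs, noise, fs, 50, events = ev,
                                       restrict = "outside")$n_spikes, 2L)
  expect_error(spike_triggered_average(trs, noise, fs, 50,
                                       events = ev[0, ], restrict = "inside"),
               "spikes")
})

test_that("PPC is unbiased: mean estimate matches the squared Bessel ratio", {
  set.seed(42)
  for (kappa in c(0, 2)) {
    target <- if (kappa == 0) 0 else (besselI(kappa, 1) / besselI(kappa, 0))^2
    est <- replicate(800, rippletools:::.ppc_val(rvonmises(20, 0, kappa)))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - target), 3 * se + 1e-8)
  }
})
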