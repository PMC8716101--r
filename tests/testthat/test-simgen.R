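# Synthetic session generator: background spectra, event injection,
# locked spiking, reproducibility and conservation.

test_that("config validation rejects invalid parameters", {
  expect_error(sim_config(session_duration = -1), "positive")
  expect_error(sim_config(ripple_rate_correct = -0.1), "rates")
  expect_error(sim_config(cross_channel_alignment = 1.5), "alignment")
  expect_error(sim_config(ripple_freq_range = c(80, 600)), "Nyquist")
  expect_error(sim_config(locking_kappa = -1), "kappa")
})

test_that("background: white-noise limit, 1/f slope, line peaks", {
  cfg <- sim_config(session_duration = 60, noise_exponent = 0,
                    line_noise_amp = 0, channel_sd = 1.7, seed = 2L)
  bg <- gen_background(cfg, 1)
  expect_lt(abs(stats::var(bg$data[1, ]) - 1.7^2) / 1.7^2, 0.05)

  cfg2 <- sim_config(session_duration = 120, noise_exponent = 2,
                     line_noise_amp = 0, seed = 3L)
  bg2 <- gen_background(cfg2, 1)
  w <- welch_psd(bg2$data[1, ], 1000, seg_s = 4)
  sel <- w$freq >= 4 & w$freq <= 100
  slope <- coef(lm(log(w$psd[sel]) ~ log(w$freq[sel])))[2]
  expect_lt(abs(slope - (-2)), 0.2)

  cfg3 <- sim_config(session_duration = 60, line_noise_amp = 0.5, seed = 4L)
  bg3 <- gen_background(cfg3, 1)
  w3 <- welch_psd(bg3$data[1, ], 1000, seg_s = 2)
  at60 <- w3$psd[which.min(abs(w3$freq - 60))]
  nbr <- mean(w3$psd[abs(w3$freq - 60) > 2 & abs(w3$freq - 60) < 6])
  expect_gt(at60 / nbr, 10)

  expect_error(gen_background(sim_config(session_duration = 0)), "positive")
})

test_that("ripple injection: zero rate, Poisson count, overlap-free truth", {
  cfg0 <- sim_config(session_duration = 20, n_mea_channels = 1,
                     ripple_rate_correct = 0, ripple_rate_incorrect = 0,
                     cross_channel_alignment = 0, seed = 5L)
  bg <- gen_background(cfg0, 1)
  inj <- inject_ripples(bg, cfg0)
  expect_identical(inj$ts$data, bg$data)
  expect_equal(nrow(inj$truth), 0L)

  cfg <- sim_config(session_duration = 600, n_mea_channels = 1,
                    ripple_rate_correct = 0.5, cross_channel_alignment = 0,
                    seed = 6L)
  bg <- gen_background(cfg, 1)
  inj <- suppressMessages(inject_ripples(bg, cfg))
  expect_lt(abs(nrow(inj$truth) - 300), 3 * sqrt(300))

  tr <- inj$truth
  o <- order(tr$window_start)
  expect_true(all(diff(tr$window_start[o]) >
                    (tr$window_end[o] - tr$window_start[o])[-nrow(tr)] * 0 - 1))
  expect_true(all(tr$window_end[o][-nrow(tr)] < tr$window_start[o][-1L]))
  expect_true(all(tr$window_start >= 1 & tr$window_end <= n_samples(bg)))
})

test_that("full phase alignment gives near-identical across-channel phase", {
  cfg <- sim_config(session_duration = 60, n_mea_channels = 8,
                    cross_channel_alignment = 1,
                    ripple_amp_dist = list(meanlog = log(20), sdlog = 0.1),
                    ripple_dur_dist = list(shape = 3, mean_ms = 80, floor_ms = 50),
                    ied_rate = 0, seed = 7L)
  bg <- gen_background(cfg, 8)
  inj <- suppressMessages(inject_ripples(bg, cfg))
  ph <- band_filter_hilbert(inj$ts, band = c(80, 120))$phase
  tr <- inj$truth[inj$truth$channel == 1L, ]
  circ_sd <- vapply(tr$center_sample, function(cs) {
    v <- exp(1i * ph[, cs])
    sqrt(-2 * log(Mod(mean(v))))
  }, numeric(1))
  expect_lt(stats::median(circ_sd), 0.1)
})

test_that("locked spikes: kappa 0 uniform, kappa 5 resultant, baseline Poisson", {
  # kappa = 0: in-event phases uniform
  cfg <- sim_config(session_duration = 120, n_mea_channels = 1,
                    cross_channel_alignment = 0, locking_kappa = 0,
                    spike_baseline_rate = 0, spike_burst_rate = 150,
                    ripple_amp_dist = list(meanlog = log(20), sdlog = 0.1),
                    ripple_dur_dist = list(shape = 3, mean_ms = 80, floor_ms = 50),
                    ied_rate = 0, seed = 8L)
  bg <- gen_background(cfg, 1)
  inj <- suppressMessages(inject_ripples(bg, cfg))
  sp <- gen_locked_spikes(inj$truth, cfg, n_samples(bg))[[1]]
  ph <- band_filter_hilbert(inj$ts$data[1, ], 1000, c(80, 120))$phase
  expect_gt(length(sp$samples), 200)
  expect_gt(rayleigh_test(ph[sp$samples])$p, 0.01)

  # kappa = 5: resultant length close to the Bessel ratio I1(5)/I0(5).
  # Carriers at the band center so that measured signal phase is not
  # distorted by band-edge filter truncation of the burst sidebands.
  cfg5 <- sim_config(session_duration = 120, n_mea_channels = 1,
                     cross_channel_alignment = 0, locking_kappa = 5,
                     spike_baseline_rate = 0, spike_burst_rate = 150,
                     ripple_freq_range = c(90, 110),
                     ripple_amp_dist = list(meanlog = log(40), sdlog = 0.1),
                     ripple_dur_dist = list(shape = 3, mean_ms = 80, floor_ms = 50),
                     ied_rate = 0, seed = 9L)
  bg5 <- gen_background(cfg5, 1)
  inj5 <- suppressMessages(inject_ripples(bg5, cfg5))
  sp5 <- gen_locked_spikes(inj5$truth, cfg5, n_samples(bg5))[[1]]
  ph5 <- band_filter_hilbert(inj5$ts$data[1, ], 1000, c(80, 120))$phase
  r5 <- rayleigh_test(ph5[sp5$samples])
  bessel <- besselI(5, 1) / besselI(5, 0)
  expect_lt(abs(r5$r_bar - bessel), 0.05)
  # preferred phase at the trough (pi), wrapped distance
  expect_lt(abs(wrap_phase(r5$preferred_phase - pi)), 0.3)

  # baseline only: Poisson count
  cfgb <- sim_config(session_duration = 100, n_mea_channels = 1,
                     ripple_rate_correct = 0, ripple_rate_incorrect = 0,
                     cross_channel_alignment = 0, spike_baseline_rate = 2,
                     seed = 10L)
  spb <- gen_locked_spikes(data.frame(channel = integer(0)), cfgb, 100000,
                           channels = 1L)[[1]]
  expect_lt(abs(length(spb$samples) - 200), 3 * sqrt(200))

  cfg_bad <- cfg
  cfg_bad$locking_kappa <- -2
  expect_error(gen_locked_spikes(inj$truth, cfg_bad, 1000), "kappa")
})

test_that("sessions are reproducible and conserve ground truth", {
  cfg <- tiny_sim_config(seed = 11L)
  s1 <- suppressMessages(build_session(cfg))
  s2 <- suppressMessages(build_session(cfg))
  expect_identical(s1$lfp$data, s2$lfp$data)
  expect_identical(s1$ieeg$data, s2$ieeg$data)
  expect_identical(lapply(s1$spikes, `[[`, "samples"),
                   lapply(s2$spikes, `[[`, "samples"))
  expect_identical(s1$truth$ripples, s2$truth$ripples)

  # conservation: recorded spike counts match trains; events inside session
  expect_identical(s1$truth$spike_counts,
                   vapply(s1$spikes, function(s) length(s$samples), integer(1)))
  expect_true(all(s1$truth$ripples$window_end <= n_samples(s1$lfp)))

  # different seed changes the session
  s3 <- suppressMessages(build_session(tiny_sim_config(seed = 12L)))
  expect_false(identical(s1$lfp$data, s3$lfp$data))
})

test_that("increasing locking kappa increases in-event spike PPC", {
  base <- function(k, seed) {
    cfg <- sim_config(session_duration = 90, n_mea_channels = 1,
                      cross_channel_alignment = 0, locking_kappa = k,
                      spike_baseline_rate = 0, spike_burst_rate = 50,
                      ripple_amp_dist = list(meanlog = log(6), sdlog = 0.2),
                      ied_rate = 0, seed = seed)
    bg <- gen_background(cfg, 1)
    inj <- suppressMessages(inject_ripples(bg, cfg))
    sp <- gen_locked_spikes(inj$truth, cfg, n_samples(bg))[[1]]
    ph <- band_filter_hilbert(inj$ts$data[1, ], 1000, c(80, 120))$phase
    ppc(ph[sp$samples])$ppc
  }
  vals <- vapply(c(0.5, 2, 8), base, numeric(1), seed = 13L)
  expect_true(all(diff(vals) > 0))
})

test_that("mixing weight 0 decouples iEEG from the array", {
  cfg <- sim_config(session_duration = 60, n_mea_channels = 4,
                    n_ieeg_channels = 1, ieeg_mixing_weight = 0,
                    ied_rate = 0, seed = 14L)
  ses <- suppressMessages(build_session(cfg))
  r <- cor(ses$ieeg$data[1, ], colMeans(ses$lfp$data))
  expect_lt(abs(r), 0.05)
})

test_that("clean sessions produce an almost empty artifact mask, IEDs are caught", {
  cfg <- tiny_sim_config(seed = 15L, ied_rate = 0)
  ses <- suppressMessages(build_session(cfg))
  m <- mask_transient_artifacts(ses$ieeg)
  expect_lt(mean(m$mask), 0.02)

  cfg2 <- tiny_sim_config(seed = 16L, ied_rate = 0.2)
  ses2 <- suppressMessages(build_session(cfg2))
  m2 <- mask_transient_artifacts(ses2$ieeg)
  flagged <- vapply(ses2$truth$ied_samples, function(s) all(m2$mask[, s]),
                    logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("session export writes plain-text tables", {
  cfg <- tiny_sim_config(seed = 17L)
  ses <- suppressMessages(build_session(cfg))
  d <- tempfile()
  paths <- write_session_tsv(ses, d)
  expect_true(all(file.exists(paths)))
  tr <- read.delim(file.path(d, "truth_ripples.tsv"))
  expect_equal(nrow(tr), nrow(ses$truth$ripples))
  unlink(d, recursive = TRUE)
})
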