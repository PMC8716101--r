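# Correlograms, shift predictors, synchrony/coincidence/burst metrics,
# windowed correlations, circular-shift nulls, Fisher z.

fs <- 1000

mk_trials <- function(k = 30, len = 4000)
  trial_table(seq(1, by = len, length.out = k),
              seq(len + 1, by = len, length.out = k))

mk_events <- function(peaks) {
  data.frame(channel = 1L, start_sample = peaks - 5L, end_sample = peaks + 5L,
             peak_sample = as.integer(peaks), peak_z = 3, duration_ms = 10,
             band_lo = 80, band_hi = 120)
}

rand_events <- function(trials, rate_per_trial = 3) {
  peaks <- unlist(mapply(function(s, e) {
    k <- rpois(1, rate_per_trial)
    sort(sample(s:(e - 1), min(k, e - s)))
  }, trials$start_sample, trials$end_sample, SIMPLIFY = FALSE))
  mk_events(peaks)
}

test_that("cross-correlogram localizes shifts and excludes self-pairs", {
  trials <- mk_trials(5)
  a <- mk_events(c(500, 1500, 4500, 9000, 13000))
  cc_shift <- event_cross_correlogram(a, within(a, peak_sample <- peak_sample + 20L),
                                      trials, fs)
  expect_equal(cc_shift$lags_ms[which.max(cc_shift$counts)], 20)

  cc_auto <- event_cross_correlogram(a, a, trials, fs)
  expect_equal(cc_auto$counts[cc_auto$lags_ms == 0], 0)  # self-pairs excluded
  # symmetric tails
  expect_equal(cc_auto$counts, rev(cc_auto$counts))

  expect_warning(event_cross_correlogram(a[0, ], a, trials, fs), "empty")

  # conservation: total count equals the number of admissible pairs
  set.seed(51)
  b <- rand_events(trials)
  cc <- event_cross_correlogram(a, b, trials, fs, max_lag_ms = 1e5)
  npairs <- sum(vapply(seq_len(nrow(trials)), function(ti) {
    na <- sum(a$peak_sample >= trials$start_sample[ti] &
                a$peak_sample < trials$end_sample[ti])
    nb <- sum(b$peak_sample >= trials$start_sample[ti] &
                b$peak_sample < trials$end_sample[ti])
    na * nb
  }, numeric(1)))
  expect_equal(sum(cc$counts), npairs)
})

test_that("independent event trains give a flat correlogram", {
  set.seed(52)
  trials <- mk_trials(50)
  a <- rand_events(trials, 5)
  b <- rand_events(trials, 5)
  cc <- event_cross_correlogram(a, b, trials, fs, max_lag_ms = 100, bin_ms = 20)
  expect_gt(stats::chisq.test(cc$counts)$p.value, 0.01)
})

test_that("shift predictor: stimulus-locked vs trial-coupled structure, permutation symmetry", {
  set.seed(53)
  trials <- mk_trials(40)
  # stimulus-locked but trial-independent: events at a fixed latency + jitter
  lockA <- mk_events(trials$start_sample + 800L +
                       sample(-150:150, nrow(trials), TRUE))
  lockB <- mk_events(trials$start_sample + 820L +
                       sample(-150:150, nrow(trials), TRUE))
  truecc <- event_cross_correlogram(lockA, lockB, trials, fs, 200, 10)
  pred <- shift_predictor(lockA, lockB, trials, fs, 200, 10)
  ratio <- synchronization_metric(truecc, pred, window_ms = 200)
  expect_lt(abs(ratio - 1), 0.35)

  # trial-coupled at lag 0: predictor lacks the central peak
  peaks <- trials$start_sample + sample(500:3500, nrow(trials), TRUE)
  coupA <- mk_events(peaks)
  coupB <- mk_events(peaks + 5L)
  t2 <- event_cross_correlogram(coupA, coupB, trials, fs, 200, 10)
  p2 <- shift_predictor(coupA, coupB, trials, fs, 200, 10)
  expect_gt(synchronization_metric(t2, p2, window_ms = 50), 2)

  # permuting trial order leaves the predictor unchanged
  perm <- sample.int(nrow(trials))
  tr_perm <- trials[perm, ]
  p3 <- shift_predictor(coupA, coupB, tr_perm, fs, 200, 10)
  expect_equal(p3$counts, p2$counts, tolerance = 1e-12)

  expect_error(shift_predictor(coupA, coupB, trials[1, ], fs), "2 trials")
})

test_that("synchronization metric: identity, linearity, scale invariance", {
  set.seed(54)
  trials <- mk_trials(30)
  a <- rand_events(trials, 4)
  cc <- event_cross_correlogram(a, rand_events(trials, 4), trials, fs)
  expect_equal(synchronization_metric(cc, cc), 1)

  cc2 <- cc
  sel <- abs(cc$lags_ms) <= 50
  cc2$counts[sel] <- 2 * cc2$counts[sel]
  expect_equal(synchronization_metric(cc2, cc), 2)

  cc3 <- cc; cc4 <- cc
  cc3$counts <- 3.7 * cc3$counts; cc4$counts <- 3.7 * cc4$counts
  expect_equal(synchronization_metric(cc3, cc4),
               synchronization_metric(cc, cc))

  ccz <- cc; ccz$counts[] <- 0
  expect_error(synchronization_metric(cc, ccz), "zero predictor")
})

test_that("circular-shift coincidence sits at chance for independent trains and is reproducible", {
  set.seed(55)
  trials <- mk_trials(40, len = 1000)
  lfp_ev <- rand_events(trials, 10)
  ieeg_ev <- rand_events(trials, 10)
  co <- circular_shift_coincidence(lfp_ev, ieeg_ev, trials, fs,
                                   n_shift = 100, seed = 9L)
  expect_gt(co$ratio, 0.8)
  expect_lt(co$ratio, 1.2)
  co2 <- circular_shift_coincidence(lfp_ev, ieeg_ev, trials, fs,
                                    n_shift = 100, seed = 9L)
  expect_identical(co$ratio, co2$ratio)
  expect_error(circular_shift_coincidence(lfp_ev[0, ], ieeg_ev, trials, fs),
               "no events")
})

test_that("coincidence exceeds chance when the macro scale mixes the micro scale", {
  cfg <- sim_config(session_duration = 90, n_mea_channels = 4,
                    n_ieeg_channels = 1, cross_channel_alignment = 0.8,
                    ied_rate = 0, seed = 56L)
  ses <- suppressMessages(build_session(cfg))
  lfp_ev <- detect_ripples(ses$lfp, detection_params(preset = "relaxed"))
  ieeg_ev <- detect_ripples(ses$ieeg, detection_params(preset = "relaxed"))
  co <- circular_shift_coincidence(lfp_ev, ieeg_ev, ses$trials, fs,
                                   n_shift = 60, seed = 2L)
  expect_gt(co$ratio, 1.3)
})

test_that("population burst metric: chance for Poisson spiking, 0 without in-ripple spikes", {
  set.seed(57)
  n <- 120000
  trains <- lapply(1:5, function(u)
    spike_train(u, sort(sample.int(n, 2000)), fs))
  peaks <- sort(sample(seq(2000, n - 2000, by = 700), 60))
  ev <- data.frame(channel = 1L, start_sample = peaks - 50L,
                   end_sample = peaks + 50L, peak_sample = peaks,
                   peak_z = 3, duration_ms = 100, band_lo = 80, band_hi = 120)
  bm <- population_burst_metric(trains, ev, n, fs, seed = 3L)
  expect_gt(bm$ratio, 0.75)
  expect_lt(bm$ratio, 1.3)

  # all spikes far away from events -> zero in-ripple mass
  far <- list(spike_train("u", c(100L, 150L, 200L), fs))
  ev2 <- mk_events(c(50000L, 60000L))
  bm2 <- population_burst_metric(far, ev2, n, fs, seed = 3L)
  expect_equal(bm2$ratio, 0)

  # bursty in-ripple spiking raises the metric
  cfg <- sim_config(session_duration = 90, n_mea_channels = 4,
                    n_ieeg_channels = 1, cross_channel_alignment = 0.8,
                    spike_burst_rate = 60, ied_rate = 0, seed = 58L)
  ses <- suppressMessages(build_session(cfg))
  ieeg_ev <- detect_ripples(ses$ieeg, detection_params(preset = "relaxed"))
  bm3 <- population_burst_metric(ses$spikes, ieeg_ev, n_samples(ses$lfp), fs,
                                 seed = 4L)
  expect_gt(bm3$ratio, 1)
})

test_that("windowed amplitude-rate correlation behaves across regimes", {
  set.seed(59)
  x <- rnorm(60000)
  expect_equal(windowed_amplitude_spike_correlation(x, x, fs)$r, 1,
               tolerance = 1e-12)
  y <- rnorm(60000)
  expect_lt(abs(windowed_amplitude_spike_correlation(x, y, fs)$r), 0.1)

  # windows built from correlated pairs recover rho
  rho <- 0.6
  nw <- 500
  a <- rnorm(nw)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(nw)
  A <- rep(a, each = 100); B <- rep(b, each = 100)
  est <- windowed_amplitude_spike_correlation(A, B, fs)$r
  expect_lt(abs(est - rho), 0.06 + 2 / sqrt(nw))

  expect_error(windowed_amplitude_spike_correlation(x[1:150], y[1:150], fs),
               "3 windows")
})

test_that("circular-shift spike null: detects true coupling, calibrated p, shift 0 excluded", {
  # statistic: correlation between per-event amplitude and in-event spike count
  cfg <- sim_config(session_duration = 120, n_mea_channels = 4,
                    cross_channel_alignment = 0, spike_burst_rate = 60,
                    ripple_amp_dist = list(meanlog = log(2.5), sdlog = 0.6),
                    ied_rate = 0, seed = 60L)
  ses <- suppressMessages(build_session(cfg))
  tr <- ses$truth$ripples
  statf <- function(trains) {
    counts <- vapply(seq_len(nrow(tr)), function(i) {
      s <- trains[[tr$channel[i]]]$samples
      sum(s >= tr$start_sample[i] & s <= tr$end_sample[i])
    }, numeric(1))
    suppressWarnings(cor(tr$amplitude, counts))
  }
  out <- circular_shift_correlation_null(statf, ses$spikes, ses$trials,
                                         n_perm = 60, seed = 5L)
  expect_gt(out$r_true, out$null_mean)
  expect_lt(out$p, 0.05)

  # independence: p roughly uniform over repeated small runs
  set.seed(61)
  n <- 40000
  trials <- mk_trials(10)
  ev_fix <- mk_events(sort(sample(seq(1000, n - 1000, by = 450), 50)))
  amp <- rnorm(nrow(ev_fix))^2 + 1
  ps <- replicate(60, {
    trains0 <- list(spike_train(1L, sort(sample.int(n, 300)), fs))
    st <- function(tl) {
      cnt <- vapply(seq_len(nrow(ev_fix)), function(i)
        sum(tl[[1]]$samples >= ev_fix$start_sample[i] &
              tl[[1]]$samples <= ev_fix$end_sample[i]), numeric(1))
      suppressWarnings(cor(amp, cnt))
    }
    circular_shift_correlation_null(st, trains0, trials, n_perm = 39,
                                    seed = sample.int(1e6, 1))$p
  })
  # de-discretize the (b+1)/(n+1) p-values before the KS check
  ps_rand <- ps - runif(length(ps)) / 40
  expect_gt(ks.test(ps_rand, "punif")$p.value, 0.01)

  expect_warning(circular_shift_correlation_null(statf, ses$spikes,
                                                 ses$trials, n_perm = 5),
                 "permutations")
})

test_that("phase-series circular-shift null is reproducible and centered", {
  set.seed(62)
  ph <- matrix(runif(4 * 20000, -pi, pi), nrow = 4)
  ev <- mk_events(sort(sample(seq(500, 19500, by = 400), 30)))
  statf <- function(pm) mean(ripple_alignment_ppc(ev, pm)$max_ppc)
  out <- circular_shift_phase_null(statf, ph, ev, n_perm = 30, seed = 6L)
  out2 <- circular_shift_phase_null(statf, ph, ev, n_perm = 30, seed = 6L)
  expect_identical(out$null, out2$null)
  expect_gt(out$p, 0.05)  # no structure to detect
})

test_that("Fisher z matches atanh and its symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.37), -fisher_z(0.37), tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})
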