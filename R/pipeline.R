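# End-to-end orchestration: simulate -> preprocess -> detect -> HFA with
# ripple-removal control -> windowed correlations -> PPC analyses -> cross-
# scale synchrony -> dip -> meta-analysis across simulated participants.

#' Pipeline configuration
#'
#' Bundles the simulation settings, detection presets and analysis toggles
#' of a full synthetic reproduction run. The default run size (six
#' participants, 120 s / 12-channel sessions, 24 spike-field frequencies)
#' is a desk-scale choice documented in the methods vignette; every
#' analysis parameter retains its reference default (80-120 Hz band, 2/3 SD
#' thresholds, 25 ms minimum duration, 15 ms join gap, +/- 50 ms and
#' +/- 25 ms synchrony windows, 200-bin dip PDFs).
#'
#' @param sim a [sim_config()] used for every participant (the seed is
#'   offset per participant).
#' @param strict,relaxed [detection_params()] presets.
#' @param n_participants number of simulated participants.
#' @param seed master seed.
#' @param ppc_freqs spike-field PPC frequency grid, Hz.
#' @param n_shuffle trial shuffles for PPC z-scoring.
#' @param n_shift circular shifts for the cross-scale coincidence null.
#' @param n_perm_corr circular-shift permutations behind the r-equivalent.
#' @param dip_n_null uniform PDFs behind the dip z-score.
#' @param analyses character vector of analysis toggles, any of `"hfa"`,
#'   `"ppc"`, `"sync"`, `"dip"`, `"meta"`.
#' @param out_dir optional directory for JSON/CSV outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(session_duration = 120,
                                             n_mea_channels = 12,
                                             n_ieeg_channels = 2),
                            strict = detection_params(preset = "strict"),
                            relaxed = detection_params(preset = "relaxed"),
                            n_participants = 6,
                            seed = 1L,
                            ppc_freqs = exp(seq(log(2), log(400),
                                                length.out = 24)),
                            n_shuffle = 100,
                            n_shift = 200,
                            n_perm_corr = 100,
                            dip_n_null = 2000,
                            analyses = c("hfa", "ppc", "sync", "dip", "meta"),
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

.config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 977)) %%
            .Machine$integer.max)
}

#' Run the full synthetic analysis pipeline
#'
#' For each simulated participant: builds a session, cleans both scales
#' (line-noise regression, local detrend, transient-artifact masking),
#' detects ripples at both scales under the strict and relaxed presets,
#' computes HFA and its ripple-removal control (HFA recomputed after
#' excising the sample indices of detected ripples), windowed
#' amplitude-rate correlations with circular-shift nulls, spike-field PPC
#' spectra z-scored by trial shuffling, across-channel ripple-alignment
#' PPC, cross-scale synchrony (shift predictor and circular-shift
#' coincidence), the population burst metric, and the dip bimodality test
#' on the population rate. Across participants it runs the cluster
#' permutation on z-scored PPC and the REML random-effects meta-analysis of
#' the amplitude-rate effect.
#'
#' Note: the common average reference is not applied to the synthetic iEEG
#' because with few channels sharing true ensemble signal it would subtract
#' the signal itself (see the methods vignette).
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with per-participant and group
#'   results; written to `out_dir` as JSON/CSV when configured.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  per <- vector("list", config$n_participants)
  z_ppc <- NULL
  effects <- NULL
  for (p in seq_len(config$n_participants)) {
    sim <- config$sim
    sim$seed <- sub_seed(config$seed, paste0("participant", p))
    ses <- stage("simulate", build_session(sim))
    fs <- ses$lfp$fs
    n <- n_samples(ses$lfp)
    res <- list(participant = p, seed = sim$seed)

    # --- preprocess ---------------------------------------------------
    ieeg <- stage("preprocess", detrend_slow(remove_line_noise(ses$ieeg)))
    lfp <- stage("preprocess", detrend_slow(remove_line_noise(ses$lfp)))
    mask_i <- stage("preprocess", mask_transient_artifacts(ieeg))
    mask_l <- stage("preprocess", mask_transient_artifacts(lfp))

    # --- detection ----------------------------------------------------
    ev <- stage("detect", list(
      ieeg_strict = detect_ripples(ieeg, config$strict, mask_i),
      ieeg_relaxed = detect_ripples(ieeg, config$relaxed, mask_i),
      lfp_strict = detect_ripples(lfp, config$strict, mask_l),
      lfp_relaxed = detect_ripples(lfp, config$relaxed, mask_l)))
    res$n_events <- vapply(ev, nrow, integer(1))
    rr <- stage("detect", ripple_raster_rate(ev$ieeg_strict, ses$trials, fs,
                                             channel = 1L))
    res$ieeg_ripple_rate <- rr$mean_rate / max(1L, n_channels(ieeg))
    res$lfp_ripple_rate <-
      ripple_raster_rate(ev$lfp_strict, ses$trials, fs)$mean_rate /
      max(1L, n_channels(lfp))

    # --- HFA + ripple-removal control ---------------------------------
    if ("hfa" %in% config$analyses) res$hfa <- stage("hfa", {
      tfr <- zscore_tfr(morlet_tfr(ieeg$data[1L, ], fs,
                                   freqs = seq(70, 200, length.out = 27)))
      ev1 <- ev$ieeg_strict[ev$ieeg_strict$channel == 1L, , drop = FALSE]
      rip_idx <- unlist(mapply(function(s, e) s:(e - 1L), ev1$start_sample,
                               ev1$end_sample, SIMPLIFY = FALSE))
      h_orig <- hfa_timeseries(tfr)
      h_ctrl <- hfa_timeseries(tfr, exclude_samples = rip_idx)
      tm <- function(h) vapply(seq_len(nrow(ses$trials)), function(ti) {
        sel <- h$time_s * fs + 1 >= ses$trials$start_sample[ti] &
          h$time_s * fs + 1 < ses$trials$end_sample[ti]
        mean(h$hfa[1L, sel], na.rm = TRUE)
      }, numeric(1))
      per_orig <- tm(h_orig); per_ctrl <- tm(h_ctrl)
      nev_tr <- vapply(seq_len(nrow(ses$trials)), function(ti)
        sum(ev1$peak_sample >= ses$trials$start_sample[ti] &
              ev1$peak_sample < ses$trials$end_sample[ti]), numeric(1))
      hi <- nev_tr > stats::median(nev_tr)
      list(trial_hfa = per_orig, trial_hfa_control = per_ctrl,
           high_ripple_trials = hi,
           removal_effect = mean((per_orig - per_ctrl)[hi], na.rm = TRUE))
    })

    # --- windowed amplitude/rate correlation --------------------------
    bh <- stage("sync", band_filter_hilbert(lfp, band = config$strict$band))
    pop_rate <- stage("sync", {
      r <- Reduce(`+`, lapply(ses$spikes, smoothed_spike_rate, n_samples = n))
      r / length(ses$spikes)
    })
    amp_mean <- colMeans(bh$amplitude)
    wc <- stage("sync", windowed_amplitude_spike_correlation(
      amp_mean, pop_rate, fs))
    res$amp_rate_r <- wc$r
    res$amp_rate_fisher_z <- fisher_z(wc$r)

    if ("meta" %in% config$analyses) {
      nullw <- stage("meta", circular_shift_correlation_null(
        function(trs) {
          rr <- Reduce(`+`, lapply(trs, smoothed_spike_rate, n_samples = n)) /
            length(trs)
          windowed_amplitude_spike_correlation(amp_mean, rr, fs)$r
        }, ses$spikes, ses$trials, n_perm = config$n_perm_corr,
        seed = sub_seed(sim$seed, "metanull")))
      res$amp_rate_p <- nullw$p
      effects <- rbind(effects, effect_record(p, nullw$r_true, nullw$null,
                                              wc$n_windows))
    }

    # --- PPC ----------------------------------------------------------
    if ("ppc" %in% config$analyses) {
      res$ppc <- stage("ppc", {
        zs <- zscore_ppc_by_trial_shuffle(
          ses$spikes, lfp, ses$trials, freqs = config$ppc_freqs,
          n_shuffle = config$n_shuffle, seed = sub_seed(sim$seed, "ppcshuffle"))
        align <- ripple_alignment_ppc(ev$ieeg_relaxed[ev$ieeg_relaxed$channel == 1L, ,
                                                      drop = FALSE], bh$phase)
        list(freqs = zs$freqs, z = zs$z, observed = zs$observed,
             alignment_mean_ppc = mean(align$max_ppc, na.rm = TRUE))
      })
      z_ppc <- rbind(z_ppc, res$ppc$z)
    }

    # --- cross-scale synchrony + bursts -------------------------------
    if ("sync" %in% config$analyses) res$sync <- stage("sync", {
      evA <- ev$lfp_strict[ev$lfp_strict$channel == 1L, , drop = FALSE]
      evB <- ev$lfp_strict[ev$lfp_strict$channel == 2L, , drop = FALSE]
      sm <- NA_real_
      if (nrow(evA) > 2L && nrow(evB) > 2L) {
        truecc <- event_cross_correlogram(evA, evB, ses$trials, fs)
        pred <- shift_predictor(evA, evB, ses$trials, fs)
        sm <- tryCatch(synchronization_metric(truecc, pred),
                       error = function(e) NA_real_)
      }
      ev_i1 <- ev$ieeg_strict[ev$ieeg_strict$channel == 1L, , drop = FALSE]
      co <- tryCatch(circular_shift_coincidence(
        ev$lfp_strict, ev_i1, ses$trials, fs, n_shift = config$n_shift,
        seed = sub_seed(sim$seed, "coinc"))$ratio, error = function(e) NA_real_)
      bm <- tryCatch(population_burst_metric(
        ses$spikes, ev$ieeg_relaxed[ev$ieeg_relaxed$channel == 1L, , drop = FALSE],
        n, fs, seed = sub_seed(sim$seed, "burst"))$ratio,
        error = function(e) NA_real_)
      list(lfp_pair_sync = sm, lfp_ieeg_coincidence = co, burst_metric = bm)
    })

    # --- dip ----------------------------------------------------------
    if ("dip" %in% config$analyses) res$dip <- stage("dip", {
      sub <- pop_rate[seq(1L, n, by = 25L)]  # 25 ms grid, decorrelated
      dz <- dip_bimodality_z(sub, n_null = config$dip_n_null,
                             seed = sub_seed(sim$seed, "dip"))
      list(z = dz$z, dip = dz$dip)
    })

    per[[p]] <- res
  }

  group <- list()
  if ("ppc" %in% config$analyses && !is.null(z_ppc) && nrow(z_ppc) >= 3L) {
    group$ppc_cluster <- cluster_permutation_across_frequencies(
      z_ppc, seed = sub_seed(config$seed, "cluster"))
    group$ppc_freqs <- config$ppc_freqs
  }
  if ("meta" %in% config$analyses && !is.null(effects) && nrow(effects) >= 2L)
    group$meta <- random_effects_meta(effects)

  out <- structure(list(per_participant = per, group = group,
                        config = config, seed = config$seed,
                        config_hash = .config_hash(config$sim)),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config$out_dir)
  out
}

.write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    slim <- res
    slim$group$meta$model <- NULL
    slim$config <- NULL
    jsonlite::write_json(slim, file.path(dir, "pipeline_report.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  if (!is.null(res$group$meta))
    utils::write.table(res$group$meta$table, file.path(dir, "forest_table.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("config_hash: %s", res$config_hash),
               sprintf("seed: %d", res$seed)),
             file.path(dir, "provenance.txt"))
  invisible(res)
}

#' Render a pipeline result as a human-readable report
#'
#' Deterministic plain-text summary of a [run_full_pipeline()] result:
#' per-participant ripple rates, correlations with their nulls,
#' PPC cluster statistics and the meta-analytic forest table.
#'
#' @param results a `pipeline_result`.
#' @return character vector of report lines (also printed).
#' @export
pipeline_report <- function(results) {
  if (is.null(results$per_participant) || !length(results$per_participant)) {
    out <- "no analyses run"
    cat(out, "\n")
    return(invisible(out))
  }
  L <- c(sprintf("== multi-scale ripple pipeline report (seed %d, config %s) ==",
                 results$seed, results$config_hash))
  for (res in results$per_participant) {
    L <- c(L, sprintf(
      "participant %d: iEEG rate %.3f Hz | LFP rate %.3f Hz | amp-rate r %.3f%s%s%s",
      res$participant, res$ieeg_ripple_rate, res$lfp_ripple_rate,
      res$amp_rate_r,
      if (!is.null(res$sync)) sprintf(" | sync %.2f coinc %.2f burst %.2f",
                                      res$sync$lfp_pair_sync,
                                      res$sync$lfp_ieeg_coincidence,
                                      res$sync$burst_metric) else "",
      if (!is.null(res$dip)) sprintf(" | dip z %.1f", res$dip$z) else "",
      if (!is.null(res$hfa)) sprintf(" | HFA removal %.3f",
                                     res$hfa$removal_effect) else ""))
  }
  if (!is.null(results$group$ppc_cluster)) {
    cl <- results$group$ppc_cluster$clusters
    if (nrow(cl)) {
      fr <- results$group$ppc_freqs
      for (i in seq_len(nrow(cl)))
        L <- c(L, sprintf("PPC cluster %.1f-%.1f Hz: stat %.1f, p = %.4g%s",
                          fr[cl$start[i]], fr[cl$end[i]], cl$stat[i], cl$p[i],
                          if (cl$significant[i]) " *" else ""))
    } else L <- c(L, "PPC cluster: none")
  }
  if (!is.null(results$group$meta)) {
    m <- results$group$meta
    L <- c(L, sprintf("meta (REML): pooled %.3f [%.3f, %.3f], tau^2 %.3f, k %d",
                      m$pooled, m$ci[1], m$ci[2], m$tau2, m$k))
    L <- c(L, sprintf("  study %s: %.3f [%.3f, %.3f]", m$table$participant,
                      m$table$effect, m$table$ci_lo, m$table$ci_hi))
  }
  cat(paste(L, collapse = "\n"), "\n")
  invisible(L)
}

#' @export
print.pipeline_result <- function(x, ...) {
  pipeline_report(x)
  invisible(x)
}
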