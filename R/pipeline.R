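## End-to-end orchestration: run every stage on a session, write stage
## outputs (CSV tables, a consolidated statistics JSON, figures) under
## an output directory. Deterministic given the config seed.

## signed-rank effect when n allows, plain median otherwise
effect_or_median <- function(diffs) {
  if (length(diffs) >= 6)
    unclass(signed_rank_effect(diffs))[c("median", "ci", "n", "p")]
  else
    list(median = stats::median(diffs), ci = c(NA_real_, NA_real_),
         n = length(diffs), p = NA_real_)
}

#' Run the full analysis pipeline on a session
#'
#' Stages: spectral band-power effects and channel map, slow-wave event
#' detection and rate change, OFF periods with the gamma-renewal null,
#' per-unit phase-locking (MI) change and inter-channel PLV, unit
#' classification and rate change, spike-history GLM comparison, sleep
#' scoring and occupancy change (when EEG/EMG present). Each stage is
#' logged; a failing stage preserves the outputs written so far and the
#' run errors after all stages have been attempted.
#'
#' @param config \code{\link{analysis_config}}
#' @param s \code{session}
#' @param out_dir output directory (created)
#' @param figures write diagnostic figures (PDF)
#' @return list of stage results (invisibly); side effect: files under
#'   \code{out_dir}
#' @export
run_pipeline <- function(config, s, out_dir, figures = TRUE) {
  validate_session(s)
  if (is.null(s$trials) || !length(s$trials$onsets)) stop("no trials")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  logf <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                              "\n", sep = "", file = logf, append = TRUE)
  failures <- character(0)
  res <- list()
  stats_json <- list()
  stage <- function(name, fn) {
    logmsg("stage ", name, " start")
    out <- tryCatch(fn(), error = function(e) {
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      failures <<- c(failures, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(out)) logmsg("stage ", name, " done")
    out
  }
  fs <- s$fs_lfp
  trials <- s$trials
  nt <- length(trials$onsets)
  pre_s <- min(config$pre_window_s, min(diff(c(0, trials$onsets))))

  res$spectral <- stage("spectral", function() {
    per_band <- list()
    for (bn in c("band_delta", "band_spindle", "band_beta_gamma",
                 "band_broadband")) {
      bp <- trial_band_powers(s$lfp[1, ], fs, trials, config[[bn]],
                              pre_s = pre_s, k = config$spectrum_k)
      per_band[[sub("band_", "", bn)]] <-
        effect_or_median(10 * log10(bp$stim / bp$pre))
    }
    map <- if (nt >= 6)
      delta_effect_map(s$lfp, fs, trials, config$band_delta,
                       alpha = config$alpha,
                       norm_thresh = config$norm_delta_thresh,
                       k = config$spectrum_k)
    else NULL
    if (!is.null(map))
      utils::write.csv(map, file.path(out_dir, "channel_map.csv"),
                       row.names = FALSE)
    stats_json$spectral <<- per_band
    list(effects = per_band, map = map)
  })

  res$events <- stage("events", function() {
    ev <- detect_slow_waves(s$lfp[1, ], fs, config$band_slow_wave,
                            config$sw_min_trough_uv, config$sw_top_pct,
                            config$sw_artifact_sd)
    utils::write.csv(as.data.frame(ev), file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    rc <- if (nrow(ev) && nt >= 6) event_rate_change(ev, trials, pre_s)
    stats_json$slow_waves <<- list(
      n_events = nrow(ev),
      rate_change = if (!is.null(rc))
        unclass(rc$effect)[c("median", "ci", "n", "p")])
    list(events = ev, rate_change = rc)
  })

  pooled <- sort(unlist(lapply(s$spikes, `[[`, "spike_times")))
  phase1 <- if (length(pooled) || figures)
    delta_phase(s$lfp[1, ], fs, config$band_delta) else NULL

  res$off <- stage("off", function() {
    if (!length(pooled)) stop("no spikes")
    op <- detect_off_periods(pooled, 0, s$duration_s,
                             config$off_kernel_sd_ms, config$off_min_dur_ms)
    phr <- phase_at(phase1, (op$start_s + op$end_s) / 2)
    utils::write.csv(cbind(as.data.frame(op), phase_rad = phr),
                     file.path(out_dir, "off_periods.csv"),
                     row.names = FALSE)
    fc <- if (nt >= 6) off_fraction_change(pooled, trials, pre_s,
                                           kernel_sd_ms = config$off_kernel_sd_ms,
                                           min_dur_ms = config$off_min_dur_ms)
    nul <- off_fraction_null(pooled, 0, s$duration_s,
                             n_sims = min(config$off_n_sims, 200),
                             seed = derive_seed(config$seed, "off_null"),
                             kernel_sd_ms = config$off_kernel_sd_ms,
                             min_dur_ms = config$off_min_dur_ms)
    pt <- if (nrow(op) >= 20) off_phase_test(op, phase1)
    stats_json$off <<- list(
      n_off = nrow(op),
      fraction_change = if (!is.null(fc))
        unclass(fc$effect)[c("median", "ci", "n", "p")],
      observed_fraction = nul$observed, null_mean = nul$null_mean,
      null_ci = nul$null_ci,
      phase_test = if (!is.null(pt)) pt[c("statistic", "dof", "p")])
    list(off = op, change = fc, null = nul, phase_test = pt)
  })

  res$phase <- stage("phase", function() {
    units <- list()
    for (u in seq_along(s$spikes)) {
      tr <- s$spikes[[u]]
      mc <- tryCatch(mi_change(tr$spike_times, phase1, trials, pre_s,
                               config$mi_spike_bins,
                               min_spikes = min(config$mi_min_spikes, 10)),
                     error = function(e) NULL)
      units[[as.character(tr$unit_id)]] <- if (!is.null(mc)) list(
        delta_mi = unclass(mc$effect)[c("median", "ci", "n", "p")],
        fraction_change = mc$fraction_change)
    }
    pl <- if (nrow(s$lfp) >= 2 && nt >= 6) {
      ph2 <- delta_phase(s$lfp[2, ], fs, config$band_delta)
      wins <- cbind(pmax(1, floor(trials$onsets * fs)),
                    pmin(ncol(s$lfp), floor(trials$offsets * fs)))
      plv(phase1$phase, ph2$phase, wins, config$plv_n_perms,
          config$plv_n_boot, seed = derive_seed(config$seed, "plv"))
    }
    stats_json$phase <<- list(
      units = units,
      plv = if (!is.null(pl)) unclass(pl)[c("plv", "offset", "p")])
    list(units = units, plv = pl)
  })

  res$units <- stage("units", function() {
    if (!length(s$spikes)) stop("no spikes")
    rows <- list(); glm_rows <- list()
    base_w <- cbind(trials$onsets - pre_s, trials$onsets)
    stim_w <- cbind(trials$onsets, trials$offsets)
    for (u in seq_along(s$spikes)) {
      tr <- s$spikes[[u]]
      cls <- as.character(classify_unit(tr$peak_to_trough_us))
      rc <- if (nt >= 6) rate_change(tr$spike_times, trials, pre_s)
      rows[[u]] <- data.frame(
        unit_id = tr$unit_id, class = cls,
        rate_pre = if (!is.null(rc)) mean(rc$rate_pre) else NA,
        rate_on = if (!is.null(rc)) mean(rc$rate_on) else NA,
        delta_rate = if (!is.null(rc)) rc$effect$median else NA,
        ci_lo = if (!is.null(rc)) rc$effect$ci[1] else NA,
        ci_hi = if (!is.null(rc)) rc$effect$ci[2] else NA,
        significant = if (!is.null(rc)) rc$significant else NA)
      fits <- tryCatch({
        fb <- fit_history_glm(tr$spike_times, base_w, config$glm_bin_ms,
                              config$glm_n_lags, config$glm_min_spikes,
                              "baseline", tr$unit_id)
        fs2 <- fit_history_glm(tr$spike_times, stim_w, config$glm_bin_ms,
                               config$glm_n_lags, config$glm_min_spikes,
                               "stim", tr$unit_id)
        list(fb, fs2)
      }, error = function(e) NULL)
      if (!is.null(fits)) {
        for (f in fits)
          glm_rows[[length(glm_rows) + 1L]] <-
            cbind(unit_id = tr$unit_id, condition = f$condition, f$coef)
      }
    }
    units_df <- do.call(rbind, rows)
    utils::write.csv(units_df, file.path(out_dir, "units.csv"),
                     row.names = FALSE)
    if (length(glm_rows))
      utils::write.csv(do.call(rbind, glm_rows),
                       file.path(out_dir, "glm.csv"), row.names = FALSE)
    stats_json$units <<- list(
      n_units = nrow(units_df),
      n_narrow = sum(units_df$class == "Narrow"),
      median_delta_rate = stats::median(units_df$delta_rate))
    units_df
  })

  if (!is.null(s$eeg) && !is.null(s$emg)) {
    res$score <- stage("score", function() {
      lab <- if (!is.null(s$state_labels)) s$state_labels
        else score_sleep(s$eeg, s$emg, s$fs_eeg,
                         emg_band = config$sleep_emg_band,
                         emg_smooth_s = config$sleep_emg_smooth_s,
                         ratio_smooth_s = config$sleep_ratio_smooth_s,
                         min_wake_s = config$sleep_min_wake_s)
      utils::write.csv(as.data.frame(lab)[c("second", "state")],
                       file.path(out_dir, "states.csv"), row.names = FALSE)
      occ <- if (nt >= 6) state_occupancy_change(lab, trials, pre_s)
      emg_eff <- if (nt >= 6) emg_power_change(s$emg, s$fs_emg, trials,
                                               config$emg_band, pre_s)
      stats_json$behavior <<- list(
        occupancy = if (!is.null(occ)) lapply(occ, function(o)
          unclass(o$effect)[c("median", "ci", "n", "p")]),
        emg_change = if (!is.null(emg_eff))
          unclass(emg_eff$effect)[c("median", "ci", "n", "p")])
      list(labels = lab, occupancy = occ, emg = emg_eff)
    })
  }

  if (figures) {
    stage("figures", function() {
      grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 9)
      on.exit(grDevices::dev.off())
      graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
      sg <- tryCatch(normalized_spectrogram(
        s$lfp[1, ], fs, trials, config$spectrogram_window_s,
        config$spectrogram_k, config$spectrogram_step_s,
        pre_s = pre_s, post_s = min(trials$offsets - trials$onsets)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(sg)) {
        sel <- sg$freqs <= 50
        graphics::image(sg$time_s, sg$freqs[sel], sg$db[, sel],
                        xlab = "time from onset (s)", ylab = "Hz",
                        main = "normalized spectrogram (dB)")
      }
      sp <- multitaper_spectrum(s$lfp[1, ], fs, config$spectrum_window_s,
                                config$spectrum_k)
      sel <- sp$freqs > 0 & sp$freqs <= 100
      graphics::plot(sp$freqs[sel], 10 * log10(sp$power[sel]), type = "l",
                     xlab = "Hz", ylab = "power (dB uV^2/Hz)",
                     main = "session spectrum")
      if (length(pooled) > 1) {
        sr <- smoothed_rate(pooled, 0, min(60, s$duration_s))
        graphics::plot(sr$time_s, sr$rate_hz, type = "l",
                       xlab = "s", ylab = "rate (Hz)",
                       main = "pooled population rate")
      }
      TRUE
    })
  }

  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(failures))
    stop("pipeline stage(s) failed: ", paste(failures, collapse = "; "))
  invisible(res)
}
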