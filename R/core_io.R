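## Domain data model and the on-disk session format.
##
## A session lives in a directory: a JSON manifest plus per-signal raw
## little-endian float32 binaries and CSV tables -- language-neutral and
## diffable. All times are seconds (float64), voltages uV, intervals
## half-open [start, end).

#' Laser trial table
#'
#' @param onsets,offsets trial start/end times (s)
#' @param power_mw per-trial laser power (mW); recycled
#' @return \code{trial_set} list
#' @export
trial_set <- function(onsets, offsets, power_mw = 1) {
  stopifnot(length(onsets) == length(offsets))
  if (any(offsets <= onsets)) stop("trial offsets must exceed onsets")
  o <- order(onsets)
  onsets <- onsets[o]; offsets <- offsets[o]
  power_mw <- rep_len(power_mw, length(onsets))[o]
  if (length(onsets) > 1) {
    gap <- onsets[-1] - offsets[-length(offsets)]
    dur <- offsets - onsets
    if (any(gap < dur[-length(dur)] - 1e-9))
      stop("inter-trial gap shorter than the stimulation duration")
  }
  structure(list(onsets = as.numeric(onsets), offsets = as.numeric(offsets),
                 power_mw = as.numeric(power_mw)),
            class = "trial_set")
}

#' Single- or multi-unit spike train
#'
#' @param unit_id identifier
#' @param spike_times strictly increasing times (s)
#' @param peak_to_trough_us waveform peak-to-trough time (us)
#' @param region "cortex" or "subcortical"
#' @param quality "single" or "multi"
#' @return \code{spike_train} list
#' @export
spike_train <- function(unit_id, spike_times, peak_to_trough_us = 300,
                        region = "cortex", quality = "single") {
  if (any(diff(spike_times) <= 0)) stop("spike times must be strictly increasing")
  if (peak_to_trough_us <= 0) stop("peak-to-trough must be positive")
  structure(list(unit_id = unit_id, spike_times = as.numeric(spike_times),
                 peak_to_trough_us = peak_to_trough_us,
                 region = match.arg(region, c("cortex", "subcortical")),
                 quality = match.arg(quality, c("single", "multi"))),
            class = "spike_train")
}

#' Recording session container
#'
#' @param lfp channels x samples matrix (uV)
#' @param fs_lfp LFP sampling rate (Hz)
#' @param eeg,emg vectors (uV)
#' @param fs_eeg,fs_emg sampling rates (Hz)
#' @param spikes list of \code{\link{spike_train}}
#' @param trials \code{\link{trial_set}}
#' @param channel_meta data.frame(channel, tag, x, y)
#' @param state_labels optional \code{sleep_labels}
#' @param name session name
#' @return validated \code{session} object
#' @export
session <- function(lfp, fs_lfp, eeg = NULL, emg = NULL, fs_eeg = fs_lfp,
                    fs_emg = fs_lfp, spikes = list(), trials = NULL,
                    channel_meta = NULL, state_labels = NULL,
                    name = "session") {
  if (is.vector(lfp)) lfp <- matrix(lfp, nrow = 1)
  if (is.null(channel_meta))
    channel_meta <- data.frame(channel = seq_len(nrow(lfp)),
                               tag = "ipsi-posterior", x = 0, y = 0)
  s <- structure(list(name = name, lfp = lfp, fs_lfp = fs_lfp,
                      eeg = eeg, emg = emg, fs_eeg = fs_eeg, fs_emg = fs_emg,
                      spikes = spikes, trials = trials,
                      channel_meta = channel_meta,
                      state_labels = state_labels,
                      duration_s = ncol(lfp) / fs_lfp),
                 class = "session")
  validate_session(s)
  s
}

validate_session <- function(s) {
  stopifnot(inherits(s, "session"))
  if (!is.matrix(s$lfp)) stop("lfp must be a channels x samples matrix")
  if (s$fs_lfp < 200)
    stop("fs_lfp must be at least 200 Hz for 70-100 Hz analyses")
  if (nrow(s$channel_meta) != nrow(s$lfp))
    stop("channel_meta rows must match LFP channels")
  dur <- s$duration_s
  if (abs(ncol(s$lfp) / s$fs_lfp - dur) > 1 / s$fs_lfp)
    stop("LFP length inconsistent with duration")
  for (tr in s$spikes) {
    if (!inherits(tr, "spike_train")) stop("spikes must be spike_train objects")
    if (length(tr$spike_times) &&
        (min(tr$spike_times) < 0 || max(tr$spike_times) > dur))
      stop("spike times outside the record")
  }
  if (!is.null(s$trials)) {
    if (any(s$trials$onsets < 0) || any(s$trials$offsets > dur))
      stop("trial intervals outside the record")
  }
  invisible(TRUE)
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("session '%s': %d LFP channel(s) x %.0f s @ %g Hz, %d unit(s), %d trial(s)\n",
              x$name, nrow(x$lfp), x$duration_s, x$fs_lfp,
              length(x$spikes),
              if (is.null(x$trials)) 0L else length(x$trials$onsets)))
  invisible(x)
}

write_f32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
}

read_f32 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 4L, endian = "little")
}

#' Write a session directory
#'
#' JSON manifest + per-signal float32 little-endian binaries + CSV
#' tables. Traces are quantised to float32 on disk.
#'
#' @param s \code{session}
#' @param path target directory (created)
#' @return \code{path}, invisibly
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- list(name = s$name, fs_lfp = s$fs_lfp, fs_eeg = s$fs_eeg,
              fs_emg = s$fs_emg, duration_s = s$duration_s,
              n_channels = nrow(s$lfp), n_samples_lfp = ncol(s$lfp),
              channel_meta = s$channel_meta,
              files = list(lfp = "lfp.f32"))
  write_f32(t(s$lfp), file.path(path, "lfp.f32"))
  if (!is.null(s$eeg)) {
    man$files$eeg <- "eeg.f32"; man$n_samples_eeg <- length(s$eeg)
    write_f32(s$eeg, file.path(path, "eeg.f32"))
  }
  if (!is.null(s$emg)) {
    man$files$emg <- "emg.f32"; man$n_samples_emg <- length(s$emg)
    write_f32(s$emg, file.path(path, "emg.f32"))
  }
  sp <- do.call(rbind, lapply(s$spikes, function(tr)
    data.frame(unit_id = tr$unit_id, time_s = tr$spike_times,
               peak_to_trough_us = tr$peak_to_trough_us,
               region = tr$region, quality = tr$quality)))
  if (!is.null(sp))
    utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  if (!is.null(s$trials))
    utils::write.csv(data.frame(onset_s = s$trials$onsets,
                                offset_s = s$trials$offsets,
                                power_mw = s$trials$power_mw),
                     file.path(path, "trials.csv"), row.names = FALSE)
  if (!is.null(s$state_labels))
    utils::write.csv(as.data.frame(s$state_labels)[c("second", "state")],
                     file.path(path, "states.csv"), row.names = FALSE)
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a session directory
#'
#' @param path session directory written by \code{\link{write_session}}
#' @return validated \code{session}
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing component: manifest.json")
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- unlist(man$files)
  for (f in need)
    if (!file.exists(file.path(path, f))) stop("missing component: ", f)
  nlfp <- man$n_channels * man$n_samples_lfp
  raw <- read_f32(file.path(path, man$files$lfp), nlfp + 1L)
  if (length(raw) != nlfp) stop("inconsistent manifest: lfp length")
  if (abs(man$n_samples_lfp / man$fs_lfp - man$duration_s) > 1 / man$fs_lfp)
    stop("inconsistent manifest: duration vs fs")
  lfp <- t(matrix(raw, nrow = man$n_samples_lfp, ncol = man$n_channels))
  eeg <- emg <- NULL
  if (!is.null(man$files$eeg)) {
    eeg <- read_f32(file.path(path, man$files$eeg), man$n_samples_eeg + 1L)
    if (length(eeg) != man$n_samples_eeg) stop("inconsistent manifest: eeg length")
  }
  if (!is.null(man$files$emg)) {
    emg <- read_f32(file.path(path, man$files$emg), man$n_samples_emg + 1L)
    if (length(emg) != man$n_samples_emg) stop("inconsistent manifest: emg length")
  }
  spikes <- list()
  spf <- file.path(path, "spikes.csv")
  if (file.exists(spf)) {
    sp <- utils::read.csv(spf)
    spikes <- lapply(split(sp, sp$unit_id), function(g)
      spike_train(g$unit_id[1], sort(g$time_s), g$peak_to_trough_us[1],
                  g$region[1], g$quality[1]))
    names(spikes) <- NULL
  }
  trials <- NULL
  trf <- file.path(path, "trials.csv")
  if (file.exists(trf)) {
    tt <- utils::read.csv(trf)
    trials <- trial_set(tt$onset_s, tt$offset_s, tt$power_mw)
  }
  labels <- NULL
  stf <- file.path(path, "states.csv")
  if (file.exists(stf)) {
    labels <- utils::read.csv(stf)
    class(labels) <- c("sleep_labels", "data.frame")
  }
  cm <- as.data.frame(man$channel_meta)
  session(lfp, man$fs_lfp, eeg, emg, man$fs_eeg, man$fs_emg,
          spikes, trials, cm, labels, man$name)
}

#' Analysis configuration with the pipeline's standard defaults
#'
#' Band edges, taper settings, detector thresholds, bootstrap counts and
#' the global seed. Per-stage seeds are derived from the global seed by
#' stable hashing of the stage name (\code{\link{derive_seed}}).
#'
#' @param ... overrides of named defaults
#' @return \code{analysis_config} list
#' @export
analysis_config <- function(...) {
  cfg <- list(
    band_delta = c(1, 4), band_spindle = c(9, 15),
    band_beta_gamma = c(15, 50), band_beta_gamma_alt = c(12, 50),
    band_high_gamma = c(70, 100), band_broadband = c(0.5, 50),
    band_slow_wave = c(0.1, 5),
    spectrum_window_s = 30, spectrum_k = 19,
    spectrogram_window_s = 5, spectrogram_k = 5, spectrogram_step_s = 1,
    pre_window_s = 30,
    sw_min_trough_uv = 100, sw_top_pct = 3, sw_artifact_sd = 2000,
    off_kernel_sd_ms = 20, off_min_dur_ms = 50, off_n_sims = 1000,
    mi_spike_bins = 10, mi_gamma_bins = 100, mi_min_spikes = 30,
    plv_n_perms = 500, plv_n_boot = 500,
    glm_bin_ms = 2, glm_n_lags = 50, glm_min_spikes = 500,
    onset_alpha = 0.005, onset_bin_ms = 10, onset_n_boot = 1000,
    sleep_emg_band = c(60, 200), sleep_emg_smooth_s = 0.05,
    sleep_ratio_smooth_s = 1, sleep_min_wake_s = 5,
    emg_band = c(10, 200),
    n_boot = 1000, n_shuffles = 400,
    norm_delta_thresh = 0.02, alpha = 0.05,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "analysis_config"
  cfg
}

#' Write / read an analysis configuration (YAML)
#'
#' @param cfg \code{analysis_config}
#' @param path file path
#' @return \code{path} / \code{analysis_config}
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}
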