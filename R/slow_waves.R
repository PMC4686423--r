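## Automatic slow-wave event detection and amplitude statistics.

#' Detect slow-wave events in an LFP trace
#'
#' The LFP is bandpassed 0.1-5 Hz with a zero-phase FIR filter; local
#' minima deeper than \code{-min_trough_uv} are candidate troughs and the
#' peak-to-peak amplitude is the first subsequent local maximum minus the
#' trough. Candidates whose surrounding +/-200 ms of *raw* LFP has a
#' standard deviation above \code{artifact_sd} uV are rejected before
#' ranking. The top \code{top_pct} percent of peak-to-peak amplitudes
#' within the session are kept (exactly \code{ceiling(top_pct/100 * n)}
#' events; equal amplitudes are ordered by time).
#'
#' @param lfp raw trace (uV)
#' @param fs sampling rate (Hz)
#' @param band filter band (Hz)
#' @param min_trough_uv trough magnitude threshold (uV)
#' @param top_pct percentile of peak-to-peak amplitudes selected
#' @param artifact_sd raw-LFP SD artifact threshold (uV)
#' @return data.frame of class \code{slow_wave_events}: trough_time_s,
#'   trough_uv, peak_time_s, peak_uv, p2p_uv, percentile
#' @export
detect_slow_waves <- function(lfp, fs, band = c(0.1, 5), min_trough_uv = 100,
                              top_pct = 3, artifact_sd = 2000) {
  if (fs < 2 * band[2]) stop("sampling rate below 2x upper band edge")
  if (length(lfp) < 10 * fs) stop("record shorter than 10 s")
  filt <- fir_bandpass(lfp, fs, band[1], band[2])
  n <- length(filt)
  d <- diff(filt)
  mins <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  maxs <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  mins <- mins[filt[mins] < -min_trough_uv]
  empty <- data.frame(trough_time_s = numeric(0), trough_uv = numeric(0),
                      peak_time_s = numeric(0), peak_uv = numeric(0),
                      p2p_uv = numeric(0), percentile = numeric(0))
  class(empty) <- c("slow_wave_events", "data.frame")
  if (!length(mins) || !length(maxs)) return(empty)
  ## first local maximum after each trough
  nxt <- findInterval(mins, maxs) + 1L
  keep <- nxt <= length(maxs)
  mins <- mins[keep]; nxt <- nxt[keep]
  if (!length(mins)) return(empty)
  pk <- maxs[nxt]
  ## artifact rejection on the raw trace around the trough
  hw <- round(0.2 * fs)
  ok <- vapply(mins, function(i) {
    w <- lfp[max(1, i - hw):min(n, i + hw)]
    stats::sd(w) <= artifact_sd
  }, logical(1))
  mins <- mins[ok]; pk <- pk[ok]
  if (!length(mins)) return(empty)
  p2p <- filt[pk] - filt[mins]
  n_keep <- ceiling(top_pct / 100 * length(mins))
  ord <- order(-p2p, mins)
  sel <- sort(ord[seq_len(n_keep)])
  ev <- data.frame(trough_time_s = (mins[sel] - 1) / fs,
                   trough_uv = filt[mins[sel]],
                   peak_time_s = (pk[sel] - 1) / fs,
                   peak_uv = filt[pk[sel]],
                   p2p_uv = p2p[sel],
                   percentile = 100 * rank(p2p)[sel] / length(p2p))
  class(ev) <- c("slow_wave_events", "data.frame")
  ev
}

#' Change in slow-wave event rate across laser trials
#'
#' Events per second in each trial's stimulation window versus its
#' pre-stimulus window, summarised by signed-rank inversion.
#'
#' @param events \code{slow_wave_events}
#' @param trials \code{\link{trial_set}}
#' @param pre_s baseline window length (s)
#' @return list with \code{effect} (\code{paired_effect}) and per-trial
#'   \code{rate_pre}, \code{rate_on} (events/s)
#' @export
event_rate_change <- function(events, trials, pre_s = 30) {
  nt <- length(trials$onsets)
  if (nt < 6) stop("need at least 6 trials")
  rate_pre <- rate_on <- numeric(nt)
  for (i in seq_len(nt)) {
    on <- trials$onsets[i]; off <- trials$offsets[i]
    rate_pre[i] <- sum(events$trough_time_s %inwin% c(on - pre_s, on)) / pre_s
    rate_on[i] <- sum(events$trough_time_s %inwin% c(on, off)) / (off - on)
  }
  list(effect = signed_rank_effect(rate_on - rate_pre),
       rate_pre = rate_pre, rate_on = rate_on)
}

#' Trough and peak amplitude statistics between conditions
#'
#' Median change and CI of trough and peak amplitudes between two event
#' sets (stimulation vs baseline), paired by trial when trial indices are
#' supplied, otherwise by bootstrap over events.
#'
#' @param events_on,events_off \code{slow_wave_events} for the two
#'   conditions (both non-empty)
#' @param n_boot bootstrap resamples used when events are unpaired
#' @param seed integer seed
#' @return list with \code{trough_change}, \code{peak_change}, each a
#'   list(median, ci)
#' @export
event_amplitude_stats <- function(events_on, events_off, n_boot = 1000,
                                  seed = 1L) {
  if (!nrow(events_on) || !nrow(events_off))
    stop("both conditions must contain events")
  set.seed(seed)
  boot_med_diff <- function(a, b) {
    d0 <- stats::median(a) - stats::median(b)
    bs <- replicate(n_boot, stats::median(sample(a, replace = TRUE)) -
                            stats::median(sample(b, replace = TRUE)))
    list(median = d0, ci = unname(stats::quantile(bs, c(0.025, 0.975))))
  }
  list(trough_change = boot_med_diff(events_on$trough_uv, events_off$trough_uv),
       peak_change = boot_med_diff(events_on$peak_uv, events_off$peak_uv))
}
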