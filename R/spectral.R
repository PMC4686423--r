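## Multitaper spectra, normalized spectrograms, band-power statistics.
##
## Spectrum defaults follow the pipeline's standard settings: 19 tapers
## over 30 s windows (NW = 10) for stationary spectra, 5 tapers in 5 s
## sliding windows every 1 s (NW = 3) for spectrograms, with the
## K = 2*NW - 1 taper convention.

.taper_cache <- new.env(parent = emptyenv())

cached_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.taper_cache[[key]]))
    .taper_cache[[key]] <- dpss_tapers(n, nw, k)
  .taper_cache[[key]]
}

#' Multitaper power spectrum
#'
#' DPSS multitaper estimate with NW = (K + 1) / 2, averaged over tapers
#' and over non-overlapping windows. One-sided power density; integrating
#' \code{power * df} recovers the signal variance (Parseval).
#'
#' @param x numeric trace (microvolts)
#' @param fs sampling rate (Hz)
#' @param window_s window length (s)
#' @param k number of tapers
#' @param nw time-bandwidth product; default \code{(k + 1) / 2}
#' @return object of class \code{mt_spectrum}: \code{freqs} (Hz),
#'   \code{power} (uV^2/Hz), \code{window_s}, \code{k}, \code{nw}
#' @export
multitaper_spectrum <- function(x, fs, window_s = 30, k = 19, nw = (k + 1) / 2) {
  if (k < 1) stop("taper count K must be >= 1")
  nwin <- floor(window_s * fs)
  if (length(x) < nwin) stop("trace shorter than one window")
  tp <- cached_tapers(nwin, nw, k)
  nseg <- floor(length(x) / nwin)
  nfreq <- floor(nwin / 2) + 1L
  acc <- numeric(nfreq)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * nwin + 1L):(s * nwin)]
    for (j in seq_len(k)) {
      X <- stats::fft(seg * tp[, j])[seq_len(nfreq)]
      acc <- acc + (Mod(X)^2) / fs
    }
  }
  p <- acc / (nseg * k)
  ## fold to one-sided density
  if (nwin %% 2 == 0) {
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
  } else {
    p[2:nfreq] <- 2 * p[2:nfreq]
  }
  structure(list(freqs = (0:(nfreq - 1L)) * fs / nwin, power = p,
                 window_s = window_s, k = k, nw = nw),
            class = "mt_spectrum")
}

#' Integrated band power from a spectrum
#'
#' Sum of power density times frequency-step over grid frequencies inside
#' the band, both edges inclusive.
#'
#' @param spec \code{mt_spectrum}
#' @param band length-2 numeric (Hz)
#' @return band power (uV^2)
#' @export
band_power <- function(spec, band) {
  df <- spec$freqs[2] - spec$freqs[1]
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  sum(spec$power[sel]) * df
}

## per-trial paired band powers (uV^2) in [onset - pre_s, onset) and
## [onset, onset + stim window); returns data.frame(pre, stim)
trial_band_powers <- function(x, fs, trials, band, pre_s = 30,
                              k = 19, window_s = NULL) {
  stim_len <- min(trials$offsets - trials$onsets)
  if (is.null(window_s)) window_s <- min(pre_s, stim_len)
  pre <- stim <- numeric(length(trials$onsets))
  keep <- logical(length(pre))
  for (i in seq_along(trials$onsets)) {
    on <- trials$onsets[i]
    i0 <- floor((on - pre_s) * fs) + 1L
    i1 <- floor(on * fs)
    i2 <- floor(min(trials$offsets[i], on + pre_s) * fs)
    if (i0 < 1 || i2 > length(x)) next
    sp_pre  <- multitaper_spectrum(x[i0:i1], fs, window_s, k)
    sp_stim <- multitaper_spectrum(x[(i1 + 1L):i2], fs, window_s, k)
    pre[i] <- band_power(sp_pre, band)
    stim[i] <- band_power(sp_stim, band)
    keep[i] <- TRUE
  }
  if (!all(keep)) warning(sum(!keep), " trial(s) without a full pre-window dropped")
  data.frame(pre = pre[keep], stim = stim[keep])
}

#' Paired band-power change across laser trials
#'
#' Sums power within the band on each trial during stimulation and during
#' the immediately preceding baseline window, takes the per-trial dB
#' difference, and reports the Hodges-Lehmann median change with a 95%
#' signed-rank-inversion CI.
#'
#' @param x trace (uV)
#' @param fs sampling rate (Hz)
#' @param trials \code{\link{trial_set}}
#' @param band length-2 numeric (Hz)
#' @param pre_s baseline window length (s)
#' @param k taper count
#' @return object of class \code{band_power_effect}: per-trial dB pairs,
#'   \code{median_db}, \code{ci_db}, \code{p}, \code{band}
#' @export
band_power_change <- function(x, fs, trials, band, pre_s = 30, k = 19) {
  if (length(trials$onsets) < 6) stop("need at least 6 trials")
  bp <- trial_band_powers(x, fs, trials, band, pre_s, k)
  d <- 10 * log10(bp$stim / bp$pre)
  eff <- signed_rank_effect(d)
  structure(list(band = band,
                 pre_db = 10 * log10(bp$pre), stim_db = 10 * log10(bp$stim),
                 diffs_db = d, median_db = eff$median, ci_db = eff$ci,
                 p = eff$p, n_trials = length(d)),
            class = "band_power_effect")
}

#' @export
print.band_power_effect <- function(x, ...) {
  cat(sprintf("band %.3g-%.3g Hz: change = %.3g dB, CI = [%.3g %.3g], n = %d trials, p = %.3g\n",
              x$band[1], x$band[2], x$median_db, x$ci_db[1], x$ci_db[2],
              x$n_trials, x$p))
  invisible(x)
}

#' Trial-normalized multitaper spectrogram
#'
#' Sliding-window multitaper power around each laser onset; the median is
#' taken across trials first, then each frequency row is divided by its
#' mean over the pre-stimulus window, and the result is expressed in dB.
#' Trials without a full pre-window are dropped with a warning.
#'
#' @param x trace (uV)
#' @param fs sampling rate (Hz)
#' @param trials \code{\link{trial_set}}
#' @param window_s sliding window length (s)
#' @param k taper count
#' @param step_s window step (s)
#' @param pre_s,post_s extent around onset (s)
#' @return list with \code{time_s} (window centres, 0 = onset),
#'   \code{freqs}, \code{db} (time x freq matrix)
#' @export
normalized_spectrogram <- function(x, fs, trials, window_s = 5, k = 5,
                                   step_s = 1, pre_s = 30, post_s = 30) {
  nwin <- floor(window_s * fs)
  starts <- seq(-pre_s, post_s - window_s, by = step_s)
  keep <- trials$onsets - pre_s >= 0 &
    trials$onsets + post_s <= length(x) / fs
  if (!all(keep)) warning(sum(!keep), " trial(s) too close to record edge dropped")
  onsets <- trials$onsets[keep]
  if (!length(onsets)) stop("no trial has a full pre-stimulus window")
  nfreq <- floor(nwin / 2) + 1L
  P <- array(NA_real_, c(length(starts), nfreq, length(onsets)))
  for (tr in seq_along(onsets)) {
    for (w in seq_along(starts)) {
      i0 <- floor((onsets[tr] + starts[w]) * fs) + 1L
      seg <- x[i0:(i0 + nwin - 1L)]
      P[w, , tr] <- multitaper_spectrum(seg, fs, window_s, k)$power
    }
  }
  med <- apply(P, c(1, 2), stats::median)
  basel <- starts + window_s / 2 < 0
  ref <- colMeans(med[basel, , drop = FALSE])
  db <- 10 * log10(sweep(med, 2, ref, "/"))
  list(time_s = starts + window_s / 2,
       freqs = (0:(nfreq - 1L)) * fs / nwin, db = db,
       n_trials = length(onsets))
}

#' Per-channel delta-effect map
#'
#' Two labellings per channel: (a) Bonferroni-corrected signed-rank
#' significance of the delta band-power change across channels, and (b) a
#' normalized-delta flag, true when delta power as a fraction of 0-50 Hz
#' power rises by at least \code{norm_thresh} (default 2 percentage
#' points) from baseline to stimulation.
#'
#' @param lfp channels x samples matrix (uV)
#' @param fs sampling rate (Hz)
#' @param trials \code{\link{trial_set}}
#' @param band delta band (Hz)
#' @param total_band reference band for the normalized flag (Hz)
#' @param alpha family-wise level before correction
#' @param norm_thresh normalized-delta rise threshold (fraction)
#' @param k taper count
#' @return data.frame: channel, change_db, p, significant_a,
#'   norm_delta_change, significant_b
#' @export
delta_effect_map <- function(lfp, fs, trials, band = c(1, 4),
                             total_band = c(0, 50), alpha = 0.05,
                             norm_thresh = 0.02, k = 19) {
  if (length(trials$onsets) < 6) stop("need at least 6 trials")
  nch <- nrow(lfp)
  out <- data.frame(channel = seq_len(nch), change_db = NA_real_,
                    p = NA_real_, significant_a = FALSE,
                    norm_delta_change = NA_real_, significant_b = FALSE)
  for (ch in seq_len(nch)) {
    bp <- trial_band_powers(lfp[ch, ], fs, trials, band, k = k)
    tot <- trial_band_powers(lfp[ch, ], fs, trials, total_band, k = k)
    d <- 10 * log10(bp$stim / bp$pre)
    eff <- signed_rank_effect(d)
    out$change_db[ch] <- eff$median
    out$p[ch] <- eff$p
    nd <- mean(bp$stim / tot$stim - bp$pre / tot$pre)
    out$norm_delta_change[ch] <- nd
    out$significant_b[ch] <- nd >= norm_thresh
  }
  out$significant_a <- out$p < alpha / nch
  out
}
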