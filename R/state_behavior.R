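## EMG power, semi-automated sleep scoring, optical-flow motion scoring,
## EEG-EMG coupling and shuffled-onset controls.

#' EMG band power per non-overlapping window
#'
#' Power summed across all frequencies within the band, per window
#' (default 10-200 Hz in 1 s windows), from the windowed periodogram.
#'
#' @param emg trace (uV)
#' @param fs sampling rate (Hz); must exceed 400
#' @param band length-2 numeric (Hz)
#' @param win_s window width (s)
#' @return list: \code{time_s} (window starts), \code{power} (uV^2)
#' @export
emg_band_power <- function(emg, fs, band = c(10, 200), win_s = 1) {
  if (fs <= 400) stop("EMG sampling rate must exceed 400 Hz")
  nwin <- floor(win_s * fs)
  nw <- floor(length(emg) / nwin)
  freqs <- (0:(floor(nwin / 2))) * fs / nwin
  sel <- freqs >= band[1] & freqs <= band[2]
  p <- vapply(seq_len(nw), function(i) {
    seg <- emg[((i - 1) * nwin + 1):(i * nwin)]
    X <- stats::fft(seg - mean(seg))[seq_along(freqs)]
    sum(Mod(X)^2 / (fs * nwin) * ifelse(freqs > 0 & freqs < fs / 2, 2, 1) * (fs / nwin) * sel)
  }, numeric(1))
  list(time_s = (seq_len(nw) - 1) * win_s, power = p)
}

#' Laser-locked change in EMG band power
#'
#' Per-trial summed band power in the stimulation versus pre-stimulus
#' window (signed-rank inversion), plus a 1 s-resolution onset contrast
#' comparing the second before onset with the second after.
#'
#' @param emg trace (uV)
#' @param fs sampling rate (Hz)
#' @param trials \code{\link{trial_set}}
#' @param band length-2 numeric (Hz)
#' @param pre_s baseline window (s)
#' @return list with \code{effect} (dB change), \code{onset_effect}
#'   (dB change, first second), per-trial values
#' @export
emg_power_change <- function(emg, fs, trials, band = c(10, 200), pre_s = 30) {
  bp <- emg_band_power(emg, fs, band)
  nt <- length(trials$onsets)
  if (nt < 6) stop("need at least 6 trials")
  win_pow <- function(a, b) {
    sel <- bp$time_s >= a & bp$time_s < b
    mean(bp$power[sel])
  }
  pre <- on <- pre1 <- on1 <- numeric(nt)
  for (i in seq_len(nt)) {
    o <- trials$onsets[i]; f <- trials$offsets[i]
    pre[i] <- win_pow(o - pre_s, o); on[i] <- win_pow(o, f)
    pre1[i] <- win_pow(o - 1, o); on1[i] <- win_pow(o, o + 1)
  }
  list(effect = signed_rank_effect(10 * log10(on / pre)),
       onset_effect = signed_rank_effect(10 * log10(on1 / pre1)),
       power_pre = pre, power_on = on)
}

#' Semi-automated sleep scoring from EEG and EMG
#'
#' Wake: the 60-200 Hz EMG envelope (Gaussian-smoothed, 50 ms SD) stays
#' above \code{emg_thresh} for at least \code{min_wake_s} seconds.
#' Remaining time is split by the smoothed ratio of <4 Hz to 4-16 Hz EEG
#' power: above \code{ratio_thresh} is NREM, below is REM; REM bouts not
#' preceded by at least \code{min_nrem_s} of NREM are relabelled wake.
#' Labels are emitted per second.
#'
#' @param eeg,emg traces (uV)
#' @param fs sampling rate (Hz), shared
#' @param emg_thresh EMG envelope threshold (uV); NULL to auto-suggest
#' @param ratio_thresh EEG ratio threshold; NULL to auto-suggest
#' @param emg_band EMG band (Hz)
#' @param emg_smooth_s EMG envelope Gaussian SD (s)
#' @param ratio_smooth_s EEG ratio Gaussian SD (s)
#' @param min_wake_s minimum supra-threshold run for wake (s)
#' @param min_nrem_s NREM bout required before REM (s)
#' @return \code{sleep_labels}: data.frame(second, state) plus
#'   attributes \code{thresholds} and \code{quality} ("ok" or
#'   "no-separation")
#' @export
score_sleep <- function(eeg, emg, fs, emg_thresh = NULL, ratio_thresh = NULL,
                        emg_band = c(60, 200), emg_smooth_s = 0.05,
                        ratio_smooth_s = 1, min_wake_s = 5, min_nrem_s = 10) {
  n_sec <- floor(min(length(eeg), length(emg)) / fs)
  env <- Mod(analytic_signal(fir_bandpass(emg, fs, emg_band[1],
                                          min(emg_band[2], fs / 2 - 1),
                                          order = fs / 10)))
  env <- gaussian_smooth(env, emg_smooth_s * fs)
  lo <- Mod(analytic_signal(fir_bandpass(eeg, fs, 0.5, 4)))^2
  hi <- Mod(analytic_signal(fir_bandpass(eeg, fs, 4, 16)))^2
  ratio <- gaussian_smooth(lo, ratio_smooth_s * fs) /
    pmax(gaussian_smooth(hi, ratio_smooth_s * fs), .Machine$double.eps)
  sec_idx <- rep(seq_len(n_sec), each = fs)[seq_len(n_sec * fs)]
  env_s <- as.numeric(tapply(env[seq_len(n_sec * fs)], sec_idx, mean))
  ratio_s <- as.numeric(tapply(ratio[seq_len(n_sec * fs)], sec_idx, mean))
  quality <- "ok"
  if (is.null(emg_thresh)) {
    km <- suppressWarnings(stats::kmeans(env_s, 2, nstart = 5))
    cm <- sort(km$centers)
    emg_thresh <- mean(cm)
    if (diff(cm) < 0.25 * cm[2]) quality <- "no-separation"
  }
  if (is.null(ratio_thresh)) ratio_thresh <- stats::median(ratio_s)
  high <- env_s > emg_thresh
  wake <- runs_at_least(high, min_wake_s)
  state <- ifelse(wake, "wake", ifelse(ratio_s > ratio_thresh, "NREM", "REM"))
  ## REM must follow an NREM bout
  r <- rle(state)
  pos <- cumsum(r$lengths) - r$lengths + 1
  for (j in seq_along(r$values)) {
    if (r$values[j] == "REM") {
      ok <- j > 1 && r$values[j - 1] == "NREM" && r$lengths[j - 1] >= min_nrem_s
      if (!ok) state[pos[j]:(pos[j] + r$lengths[j] - 1)] <- "wake"
    }
  }
  out <- data.frame(second = seq_len(n_sec) - 1L, state = state)
  attr(out, "thresholds") <- c(emg = emg_thresh, ratio = ratio_thresh)
  attr(out, "quality") <- quality
  class(out) <- c("sleep_labels", "data.frame")
  out
}

## TRUE where x belongs to a run of TRUEs of length >= k
runs_at_least <- function(x, k) {
  r <- rle(x)
  r$values <- r$values & r$lengths >= k
  inverse.rle(r)
}

#' Per-state occupancy change across laser trials
#'
#' Percentage of time in each state during the stimulation versus
#' pre-stimulus window, per trial, summarised by signed-rank inversion
#' per state. Changes across the three states sum to zero per trial.
#'
#' @param labels \code{sleep_labels}
#' @param trials \code{\link{trial_set}}
#' @param pre_s baseline window (s)
#' @return named list (wake, NREM, REM) of lists with \code{effect}
#'   (percentage points) and per-trial occupancies
#' @export
state_occupancy_change <- function(labels, trials, pre_s = 30) {
  nt <- length(trials$onsets)
  if (nt < 6) stop("need at least 6 trials")
  states <- c("wake", "NREM", "REM")
  occ <- function(a, b, st) {
    sel <- labels$second >= a & labels$second < b
    100 * mean(labels$state[sel] == st)
  }
  out <- list()
  for (st in states) {
    pre <- on <- numeric(nt)
    for (i in seq_len(nt)) {
      o <- trials$onsets[i]; f <- trials$offsets[i]
      pre[i] <- occ(o - pre_s, o, st); on[i] <- occ(o, f, st)
    }
    out[[st]] <- list(effect = signed_rank_effect(on - pre),
                      occ_pre = pre, occ_on = on)
  }
  out
}

#' Motion trace from a grayscale frame stack via Horn-Schunck flow
#'
#' Dense optical flow for each frame pair (regularisation alpha^2 = 1,
#' 100 iterations, intensities scaled to [0, 1]); the per-frame motion
#' magnitude is that of the maximal-flow point. The trace is normalised
#' by its mean and smoothed with a moving-average filter.
#'
#' @param frames 3-D array (h x w x n) or list of matrices
#' @param smooth_frames moving-average window (frames)
#' @param alpha2 Horn-Schunck regularisation
#' @param n_iter iterations per frame pair
#' @return \code{motion_trace}: data.frame(frame, magnitude); first
#'   entry corresponds to the second frame. Attribute \code{raw} holds
#'   the pre-normalisation magnitudes.
#' @export
motion_from_frames <- function(frames, smooth_frames = 200, alpha2 = 1,
                               n_iter = 100) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (length(frames) < 2) stop("need at least 2 frames")
  rng <- range(unlist(lapply(frames, range)))
  scl <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(frames, function(f) (f - rng[1]) / scl)
  raw <- vapply(seq_len(length(frames) - 1), function(i) {
    fl <- horn_schunck(frames[[i]], frames[[i + 1]], alpha2, n_iter)
    mag <- sqrt(fl$u^2 + fl$v^2)
    max(mag)
  }, numeric(1))
  m <- if (mean(raw) > 0) raw / mean(raw) else raw
  m <- moving_average(m, min(smooth_frames, length(m)))
  m <- if (mean(m) > 0) m / mean(m) else m
  out <- data.frame(frame = seq_along(m) + 1L, magnitude = m)
  attr(out, "raw") <- raw
  class(out) <- c("motion_trace", "data.frame")
  out
}

## classic Horn-Schunck iteration on one frame pair
horn_schunck <- function(f1, f2, alpha2 = 1, n_iter = 100) {
  sh <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    m[ri, ci, drop = FALSE]
  }
  Ex <- (sh(f1, 0, 1) - f1 + sh(f2, 0, 1) - f2) / 2
  Ey <- (sh(f1, 1, 0) - f1 + sh(f2, 1, 0) - f2) / 2
  Et <- f2 - f1
  u <- v <- matrix(0, nrow(f1), ncol(f1))
  lap <- function(m) (sh(m, -1, 0) + sh(m, 1, 0) + sh(m, 0, -1) + sh(m, 0, 1)) / 4
  denom <- alpha2 + Ex^2 + Ey^2
  for (it in seq_len(n_iter)) {
    ub <- lap(u); vb <- lap(v)
    t <- (Ex * ub + Ey * vb + Et) / denom
    u <- ub - Ex * t
    v <- vb - Ey * t
  }
  list(u = u, v = v)
}

#' Correlation between EEG delta and EMG power changes with a shuffle test
#'
#' Pearson r of per-trial EEG delta-power change versus EMG power
#' change; percentile bootstrap CI over paired trials; significance at
#' alpha = 0.05 by comparing |r| with the 97.5th percentile of the
#' correlation under shuffled trial pairings.
#'
#' @param delta_changes per-trial EEG delta power changes (dB)
#' @param emg_changes per-trial EMG power changes (dB)
#' @param n_boot bootstrap / shuffle iterations
#' @param seed integer seed
#' @return list: \code{r}, \code{ci}, \code{null_q975},
#'   \code{significant}
#' @export
eeg_emg_correlation <- function(delta_changes, emg_changes, n_boot = 1000,
                                seed = 1L) {
  n <- length(delta_changes)
  if (n < 10 || length(emg_changes) != n)
    stop("need at least 10 paired trials")
  r <- stats::cor(delta_changes, emg_changes)
  set.seed(seed)
  boot_r <- replicate(n_boot, {
    i <- sample.int(n, replace = TRUE)
    suppressWarnings(stats::cor(delta_changes[i], emg_changes[i]))
  })
  null_r <- replicate(n_boot, {
    suppressWarnings(stats::cor(delta_changes, emg_changes[sample.int(n)]))
  })
  q <- stats::quantile(abs(null_r), 0.975, names = FALSE)
  list(r = r, ci = unname(stats::quantile(boot_r, c(0.025, 0.975),
                                          na.rm = TRUE)),
       null_q975 = q, significant = abs(r) > q)
}

#' Shuffled-onset control for an onset-locked statistic
#'
#' Recomputes a statistic at pseudorandom onset times restricted to
#' spontaneous NREM sleep, repeated \code{n_shuffles} times, giving a
#' null distribution and its 95% interval for comparison with the
#' true-onset value.
#'
#' @param stat_fn function(onsets) -> scalar statistic
#' @param labels \code{sleep_labels}
#' @param n_onsets onsets per shuffle
#' @param margin_s seconds of NREM required around each placed onset
#' @param n_shuffles shuffle count (default 400)
#' @param seed integer seed
#' @return list: \code{null_values}, \code{null_ci}, \code{n_shuffles}
#' @export
shuffled_onset_control <- function(stat_fn, labels, n_onsets,
                                   margin_s = 30, n_shuffles = 400,
                                   seed = 1L) {
  nrem_sec <- labels$second[labels$state == "NREM"]
  ## candidate onsets: margin_s of NREM on both sides, inside the record
  cand <- nrem_sec[vapply(nrem_sec, function(s)
    all((s - margin_s):(s + margin_s) %in% nrem_sec), logical(1))]
  if (length(cand) < n_onsets) stop("not enough NREM time to place onsets")
  set.seed(seed)
  nulls <- replicate(n_shuffles, {
    stat_fn(sort(sample(cand, n_onsets)))
  })
  list(null_values = nulls,
       null_ci = unname(stats::quantile(nulls, c(0.025, 0.975))),
       n_shuffles = n_shuffles)
}
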