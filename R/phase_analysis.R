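## Delta-phase extraction, phase-locking value, KL modulation index.

#' Instantaneous delta phase of an LFP trace
#'
#' Zero-phase FIR bandpass (default 1-4 Hz), Hilbert transform, angle.
#' Samples within one filter half-length of either record edge are
#' flagged invalid. Phase convention: troughs of the filtered trace sit
#' at +/- pi, peaks at 0.
#'
#' @param lfp trace (uV)
#' @param fs sampling rate (Hz)
#' @param band length-2 numeric (Hz)
#' @return list of class \code{phase_series}: \code{phase} in [-pi, pi),
#'   \code{valid} logical, \code{fs}, \code{band}
#' @export
delta_phase <- function(lfp, fs, band = c(1, 4)) {
  order <- min(3 * fs / band[1], floor((length(lfp) - 1) / 3))
  filt <- fir_bandpass(lfp, fs, band[1], band[2])
  ph <- wrap_pi(Arg(analytic_signal(filt)))
  half <- ceiling(order / 2)
  valid <- rep(TRUE, length(ph))
  valid[seq_len(min(half, length(ph)))] <- FALSE
  valid[length(ph) - seq_len(min(half, length(ph))) + 1L] <- FALSE
  structure(list(phase = ph, valid = valid, fs = fs, band = band),
            class = "phase_series")
}

## phase at arbitrary times, NA outside the valid region
phase_at <- function(ps, times) {
  idx <- floor(times * ps$fs) + 1L
  ok <- idx >= 1L & idx <= length(ps$phase)
  out <- rep(NA_real_, length(times))
  out[ok] <- ifelse(ps$valid[idx[ok]], ps$phase[idx[ok]], NA_real_)
  out
}

#' Phase-locking value between two phase series with a permutation null
#'
#' PLV is the magnitude of the circular mean of the per-sample phase
#' difference across all in-window samples; the offset is its angle. The
#' null shuffles which trial of series b is paired with each trial of
#' series a (\code{n_perms} label shuffles); the bootstrap resamples
#' trials to give a percentile CI for the offset angle.
#'
#' @param phase_a,phase_b numeric phase vectors (rad), same sampling
#' @param windows list of length-2 numeric sample-index ranges, or a
#'   two-column matrix, one row per trial
#' @param n_perms permutation count
#' @param n_boot bootstrap resamples for the angle CI
#' @param seed integer seed
#' @return \code{plv_result}: \code{plv}, \code{offset}, \code{p},
#'   \code{offset_ci}, \code{n_perms}
#' @export
plv <- function(phase_a, phase_b, windows, n_perms = 500, n_boot = 500,
                seed = 1L) {
  if (is.matrix(windows)) windows <- asplit(windows, 1)
  nt <- length(windows)
  if (nt < 6) stop("need at least 6 trial windows")
  segs_a <- lapply(windows, function(w) phase_a[w[1]:w[2]])
  segs_b <- lapply(windows, function(w) phase_b[w[1]:w[2]])
  plv_of <- function(pa, pb) {
    z <- mean(exp(1i * (unlist(pa) - unlist(pb))))
    z
  }
  z0 <- plv_of(segs_a, segs_b)
  set.seed(seed)
  null_plv <- replicate(n_perms, {
    Mod(plv_of(segs_a, segs_b[sample.int(nt)]))
  })
  p <- (1 + sum(null_plv >= Mod(z0))) / (n_perms + 1)
  boot_ang <- replicate(n_boot, {
    i <- sample.int(nt, replace = TRUE)
    Arg(plv_of(segs_a[i], segs_b[i]))
  })
  ## percentile CI of the angle, centred on the observed offset
  dev <- wrap_pi(boot_ang - Arg(z0))
  ci <- wrap_pi(Arg(z0) + stats::quantile(dev, c(0.025, 0.975)))
  structure(list(plv = Mod(z0), offset = Arg(z0), p = p,
                 offset_ci = unname(ci), n_perms = n_perms),
            class = "plv_result")
}

#' Kullback-Leibler modulation index of a phase distribution
#'
#' Spikes are assigned to \code{n_bins} equal bins over [-pi, pi); with
#' p_i the spike share per bin, MI = sum p_i log2 p_i + log2 n_bins
#' (0 log 0 = 0). MI is 0 for a uniform distribution and log2(n_bins)
#' when one bin holds all spikes. The preferred phase is the centre of
#' the bin containing the most spikes.
#'
#' @param spike_phases phases (rad) of each spike
#' @param n_bins phase bin count (default 10)
#' @param min_spikes floor below which the estimate is refused
#' @return \code{mi_result}: \code{mi_bits}, \code{n_bins}, \code{p_i},
#'   \code{preferred_phase}, \code{n}
#' @export
spike_phase_mi <- function(spike_phases, n_bins = 10, min_spikes = 30) {
  ph <- spike_phases[is.finite(spike_phases)]
  if (!length(ph)) stop("no spikes with valid phase")
  if (length(ph) < min_spikes)
    stop("fewer spikes than the configured floor (", min_spikes, ")")
  bins <- phase_bin(ph, n_bins)
  counts <- tabulate(bins, n_bins)
  p_i <- counts / sum(counts)
  mi <- sum(ifelse(p_i > 0, p_i * log2(p_i), 0)) + log2(n_bins)
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  structure(list(mi_bits = mi, n_bins = n_bins, p_i = p_i,
                 preferred_phase = centers[which.max(counts)],
                 n = length(ph)),
            class = "mi_result")
}

## left-closed equal bins over [-pi, pi)
phase_bin <- function(ph, n_bins) {
  b <- floor((wrap_pi(ph) + pi) / (2 * pi) * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Modulation index of gamma amplitude by delta phase
#'
#' The 70-100 Hz envelope (analytic-signal magnitude of the bandpassed
#' trace) is averaged within 100 delta-phase bins; the binned profile is
#' normalised to sum to 1 and its KL modulation index computed. A
#' least-squares sinusoid A cos(phase - phi0) + c fitted to the binned
#' profile supplies the preferred phase.
#'
#' @param lfp trace (uV)
#' @param fs sampling rate (Hz); must be at least twice the upper gamma edge
#' @param gamma_band length-2 numeric (Hz)
#' @param delta_band band used for the phase (Hz)
#' @param n_bins phase bins (default 100)
#' @param phase optional precomputed \code{phase_series} for this trace
#' @return \code{mi_result} with additional fields \code{profile}
#'   (mean envelope per bin, normalised to mean 1) and \code{fit}
#'   (A, phi0, c)
#' @export
gamma_power_mi <- function(lfp, fs, gamma_band = c(70, 100),
                           delta_band = c(1, 4), n_bins = 100,
                           phase = NULL) {
  if (fs < 2 * gamma_band[2]) stop("sampling rate below 2x upper gamma edge")
  if (is.null(phase)) phase <- delta_phase(lfp, fs, delta_band)
  ## 1 s of taps: narrow transition bands and deep stopband, so the
  ## large low-frequency LFP cannot leak into the gamma envelope
  env <- Mod(analytic_signal(fir_bandpass(lfp, fs, gamma_band[1], gamma_band[2],
                                          order = fs)))
  ok <- phase$valid
  bins <- phase_bin(phase$phase[ok], n_bins)
  prof <- as.numeric(tapply(env[ok], factor(bins, levels = seq_len(n_bins)),
                            mean))
  prof[is.na(prof)] <- 0
  p_i <- prof / sum(prof)
  mi <- sum(ifelse(p_i > 0, p_i * log2(p_i), 0)) + log2(n_bins)
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  X <- cbind(1, cos(centers), sin(centers))
  cf <- stats::lsfit(X, prof, intercept = FALSE)$coefficients
  phi0 <- atan2(cf[3], cf[2])
  structure(list(mi_bits = mi, n_bins = n_bins, p_i = p_i,
                 preferred_phase = unname(phi0),
                 profile = prof / mean(prof),
                 fit = c(A = unname(sqrt(cf[2]^2 + cf[3]^2)),
                         phi0 = unname(phi0), c = unname(cf[1])),
                 n = sum(ok)),
            class = "mi_result")
}

#' Laser-locked change in a unit's spike-phase modulation index
#'
#' MI is computed per trial in the baseline ([-pre_s, 0) s relative to
#' onset) and stimulation ([0, pre_s) s) windows, and the paired
#' difference is summarised by signed-rank inversion. The fraction change
#' (MI_on - MI_pre) / MI_pre of the trial-median MIs is also reported.
#'
#' @param spike_times spike times (s)
#' @param phase \code{phase_series} for the unit's local LFP
#' @param trials \code{\link{trial_set}}
#' @param pre_s window length (s)
#' @param n_bins phase bins
#' @param min_spikes per-trial spike floor; trials below it are dropped
#' @return list with \code{effect} (\code{paired_effect}), per-trial
#'   \code{mi_pre}, \code{mi_on}, and \code{fraction_change}
#' @export
mi_change <- function(spike_times, phase, trials, pre_s = 30, n_bins = 10,
                      min_spikes = 10) {
  nt <- length(trials$onsets)
  if (nt < 6) stop("need at least 6 trials")
  mi_pre <- mi_on <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    on <- trials$onsets[i]
    for (w in 1:2) {
      win <- if (w == 1) c(on - pre_s, on) else c(on, on + pre_s)
      ph <- phase_at(phase, spike_times[spike_times %inwin% win])
      ph <- ph[is.finite(ph)]
      if (length(ph) >= min_spikes) {
        v <- spike_phase_mi(ph, n_bins, min_spikes = min_spikes)$mi_bits
        if (w == 1) mi_pre[i] <- v else mi_on[i] <- v
      }
    }
  }
  ok <- is.finite(mi_pre) & is.finite(mi_on)
  if (sum(ok) < 6) stop("fewer than 6 trials with enough spikes in both windows")
  eff <- signed_rank_effect(mi_on[ok] - mi_pre[ok])
  mp <- stats::median(mi_pre[ok])
  list(effect = eff, mi_pre = mi_pre, mi_on = mi_on,
       fraction_change = if (mp > 0) (stats::median(mi_on[ok]) - mp) / mp else NA_real_)
}

## circular kurtosis (Pewsey; the CircStat primary definition):
## k = mean(cos(2 * (alpha - mean direction)))
circular_kurtosis <- function(alpha) {
  mu <- Arg(mean(exp(1i * alpha)))
  mean(cos(2 * wrap_pi(alpha - mu)))
}

#' Compare circular kurtosis of peak phases between two unit groups
#'
#' The narrowness of each group's peak-phase distribution is measured by
#' circular kurtosis; the observed group difference is compared to a null
#' built by shuffling the unit-type assignment \code{n_boot} times, with
#' the 2.5th/97.5th percentiles of shuffled differences as the 95%
#' interval.
#'
#' @param phases_group_a,phases_group_b per-unit peak phases (rad)
#' @param n_boot shuffles
#' @param seed integer seed
#' @return list: \code{diff}, \code{null_ci}, \code{significant},
#'   \code{kurtosis_a}, \code{kurtosis_b}
#' @export
circular_kurtosis_compare <- function(phases_group_a, phases_group_b,
                                      n_boot = 1000, seed = 1L) {
  na <- length(phases_group_a); nb <- length(phases_group_b)
  if (na < 3 || nb < 3) stop("need at least 3 units per group")
  ka <- circular_kurtosis(phases_group_a)
  kb <- circular_kurtosis(phases_group_b)
  pool <- c(phases_group_a, phases_group_b)
  set.seed(seed)
  null_d <- replicate(n_boot, {
    i <- sample.int(na + nb)
    circular_kurtosis(pool[i[seq_len(na)]]) -
      circular_kurtosis(pool[i[(na + 1):(na + nb)]])
  })
  ci <- unname(stats::quantile(null_d, c(0.025, 0.975)))
  d <- ka - kb
  list(diff = d, null_ci = ci, significant = d < ci[1] || d > ci[2],
       kurtosis_a = ka, kurtosis_b = kb)
}
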