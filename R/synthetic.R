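## Synthetic sessions with ground-truth labels.
##
## Every downstream stage is verified by parameter recovery on data from
## this module: 1/f LFP background plus a laser-locked asymmetric slow
## wave with delta-phase-coupled high gamma, conditional-intensity spike
## trains (von Mises phase locking, per-2 ms history gains, forced OFF
## periods), and EEG/EMG with wake/NREM/REM structure.

#' Generate an LFP channel with a laser-locked slow-wave effect
#'
#' Background is 1/f-shaped noise (power exponent 1). During each laser
#' trial an asymmetric 1-4 Hz oscillation (fundamental plus phase-locked
#' second harmonic; troughs deeper than peaks) is added, scaled so the
#' realised delta band-power change approximates \code{delta_effect_db},
#' and the 70-100 Hz amplitude is modulated by the delta phase.
#'
#' @param duration_s record length (s)
#' @param trials \code{\link{trial_set}} of laser windows
#' @param delta_effect_db target delta band-power change (dB)
#' @param seed integer seed
#' @param fs sampling rate (Hz)
#' @param sw_freq_hz slow-wave fundamental (Hz)
#' @param asymmetry second-harmonic fraction (trough/peak asymmetry)
#' @param background_sd_uv background RMS (uV)
#' @param gamma_mod gamma amplitude modulation depth by delta phase
#' @param gamma_phase preferred delta phase of gamma amplitude (rad)
#' @param gamma_sd_uv gamma band RMS (uV)
#' @param artifacts inject >2000 uV excursions (detector tests)
#' @return list: \code{trace} (uV), \code{fs}, \code{ground_truth}
#'   (trough_times, phase series theta, delta_effect_db, asymmetry,
#'   artifact_times)
#' @export
generate_lfp <- function(duration_s, trials, delta_effect_db = 2.5,
                         seed = 1L, fs = 1000, sw_freq_hz = 1.7,
                         asymmetry = 0.3, background_sd_uv = 50,
                         gamma_mod = 0.5, gamma_phase = 0,
                         gamma_sd_uv = 5, artifacts = FALSE) {
  if (duration_s <= 0) stop("duration must be positive")
  if (max(trials$offsets) > duration_s)
    stop("duration does not cover the trials")
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- shaped_noise(n, fs, exponent = 1, sd = background_sd_uv)
  ## delta-band background power sets the oscillation scale; measured
  ## with the same multitaper band sum the analysis uses
  pb <- band_power(multitaper_spectrum(x, fs,
                                       window_s = min(30, duration_s),
                                       k = 19), c(1, 4))
  ratio <- 10^(delta_effect_db / 10)
  amp <- sqrt(max(ratio - 1, 0) * 2 * pb / (1 + asymmetry^2))
  ## slowly drifting oscillator phase, continuous across the record
  theta <- cumsum(2 * pi * (sw_freq_hz + 0.05 * sw_freq_hz *
                              gaussian_smooth(stats::rnorm(n), fs)) / fs)
  tt <- (seq_len(n) - 1) / fs
  on_mask <- rep(FALSE, n)
  for (i in seq_along(trials$onsets))
    on_mask[tt %inwin% c(trials$onsets[i], trials$offsets[i])] <- TRUE
  ramp <- gaussian_smooth(as.numeric(on_mask), 0.1 * fs)
  osc <- amp * (cos(theta) - asymmetry * cos(2 * theta)) * ramp
  ## delta-phase-modulated high gamma during stimulation
  g <- shaped_noise(n, fs, exponent = 0, sd = 1)
  g <- fir_bandpass(g, fs, 70, 100, order = 3 * fs / 70)
  g <- g / stats::sd(g) * gamma_sd_uv
  g <- g * (1 + gamma_mod * cos(theta - gamma_phase) * ramp)
  trace <- x + osc + g
  ## ground-truth troughs: oscillator phase crossing pi inside trials
  wrapped <- wrap_pi(theta)
  cross <- which(diff(wrapped) < -pi) # wrap from +pi to -pi = trough
  trough_times <- tt[cross][on_mask[cross]]
  artifact_times <- numeric(0)
  if (artifacts) {
    artifact_times <- sort(stats::runif(max(3, round(duration_s / 60)),
                                        0, duration_s - 0.5))
    for (a in artifact_times) {
      i0 <- round(a * fs) + 1L
      trace[i0:min(n, i0 + round(0.05 * fs))] <- 3000
    }
  }
  list(trace = trace, fs = fs,
       ground_truth = list(trough_times = trough_times, theta = theta,
                           delta_effect_db = delta_effect_db,
                           asymmetry = asymmetry, amp = amp,
                           gamma_mod = gamma_mod,
                           artifact_times = artifact_times))
}

## FFT-shaped noise with power ~ 1/f^exponent, scaled to the given SD
shaped_noise <- function(n, fs, exponent = 1, sd = 1) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + fs / n)
  X <- X / f^(exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y) * sd
}

#' Generate a spike train from a conditional-intensity model
#'
#' Discrete-time thinning at 1 ms: intensity = base rate x von Mises
#' phase modulation (normalised to mean 1 over uniform phase) x
#' multiplicative per-2 ms-lag history gains x an OFF-period mask that
#' forces the intensity to zero inside ground-truth OFF intervals.
#'
#' @param duration_s record length (s)
#' @param base_rate_hz baseline rate (> 0)
#' @param kappa von Mises concentration (>= 0)
#' @param phi0 preferred phase (rad)
#' @param theta oscillator phase series at \code{fs_phase} (or NULL for
#'   no phase modulation)
#' @param fs_phase sampling rate of \code{theta}
#' @param mod_mask logical at \code{fs_phase}: where phase modulation is
#'   active (e.g. laser-ON); NULL = everywhere
#' @param history_gain multiplicative gain per 2 ms history lag (numeric
#'   vector, lag 1 first), or NULL
#' @param off_periods data.frame(start_s, end_s) of forced silences
#' @param seed integer seed
#' @param unit_id,peak_to_trough_us,region,quality stored in the result
#' @return \code{spike_train} with attribute \code{ground_truth}
#' @export
generate_spike_train <- function(duration_s, base_rate_hz, kappa = 0,
                                 phi0 = pi, theta = NULL, fs_phase = 1000,
                                 mod_mask = NULL, history_gain = NULL,
                                 off_periods = NULL, seed = 1L,
                                 unit_id = 1, peak_to_trough_us = 300,
                                 region = "cortex", quality = "single") {
  if (base_rate_hz <= 0) stop("base rate must be positive")
  if (kappa < 0) stop("kappa must be non-negative")
  set.seed(seed)
  dt <- 1e-3
  n <- round(duration_s / dt)
  lam <- rep(base_rate_hz, n)
  if (kappa > 0 && !is.null(theta)) {
    idx <- pmin(floor((seq_len(n) - 0.5) * dt * fs_phase) + 1L, length(theta))
    vm <- exp(kappa * cos(theta[idx] - phi0)) / besselI(kappa, 0)
    if (!is.null(mod_mask)) {
      mm <- mod_mask[idx]
      vm[!mm] <- 1
    }
    lam <- lam * vm
  }
  if (!is.null(off_periods) && nrow(off_periods)) {
    tt <- (seq_len(n) - 0.5) * dt
    for (i in seq_len(nrow(off_periods)))
      lam[tt >= off_periods$start_s[i] & tt < off_periods$end_s[i]] <- 0
  }
  p <- pmin(lam * dt, 1)
  if (is.null(history_gain)) {
    fired <- stats::runif(n) < p
  } else {
    nl <- length(history_gain)
    fired <- logical(n)
    u <- stats::runif(n)
    lg <- log(history_gain)
    for (t in seq_len(n)) {
      g <- 0
      ## lag bin l covers spikes (2(l-1), 2l] ms back: 1 ms-grid samples
      ## t-2l and t-2l+1
      for (l in seq_len(nl)) {
        b <- t - 2 * l + 1
        if (b < 1) break
        if (any(fired[max(t - 2 * l, 1):b])) g <- g + lg[l]
      }
      fired[t] <- u[t] < min(p[t] * exp(g), 1)
    }
  }
  times <- (which(fired) - 1) * dt + stats::runif(sum(fired), 0, dt)
  times <- sort(times)
  tr <- spike_train(unit_id, times, peak_to_trough_us, region, quality)
  attr(tr, "ground_truth") <- list(base_rate_hz = base_rate_hz,
                                   kappa = kappa, phi0 = phi0,
                                   history_gain = history_gain,
                                   off_periods = off_periods)
  tr
}

#' Place ground-truth OFF periods at slow-wave troughs
#'
#' Durations are log-normal with the given median; each trough inside a
#' laser trial hosts an OFF period with probability \code{p_off}, with
#' small Gaussian timing jitter.
#'
#' @param trough_times slow-wave trough times (s)
#' @param p_off per-trough probability
#' @param median_dur_ms log-normal median duration (ms)
#' @param sdlog log-normal sdlog
#' @param jitter_ms SD of centre jitter (ms)
#' @param seed integer seed
#' @return data.frame(start_s, end_s)
#' @export
place_off_periods <- function(trough_times, p_off = 0.7,
                              median_dur_ms = 122, sdlog = 0.3,
                              jitter_ms = 20, seed = 1L) {
  set.seed(seed)
  keep <- stats::runif(length(trough_times)) < p_off
  ctr <- trough_times[keep] + stats::rnorm(sum(keep), 0, jitter_ms / 1000)
  dur <- stats::rlnorm(sum(keep), log(median_dur_ms / 1000), sdlog)
  out <- data.frame(start_s = ctr - dur / 2, end_s = ctr + dur / 2)
  out <- out[order(out$start_s), , drop = FALSE]
  ## drop overlaps (keep the earlier period)
  if (nrow(out) > 1) {
    keep2 <- c(TRUE, out$start_s[-1] >= cummax(out$end_s[-nrow(out)]))
    out <- out[keep2, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Generate EEG + EMG + labels with wake/NREM/REM structure
#'
#' EMG is broadband noise with state-dependent amplitude (high in wake);
#' EEG mixes a 1/f background with state-dependent delta (strong in
#' NREM), theta (wake/REM) and NREM spindle transients, so the <4 Hz to
#' 4-16 Hz ratio is high in NREM and low in wake/REM.
#'
#' @param epochs data.frame(state, duration_s) in temporal order; states
#'   from wake/NREM/REM
#' @param seed integer seed
#' @param fs sampling rate (Hz)
#' @param emg_sd named amplitudes (uV) per state
#' @return list: \code{eeg}, \code{emg}, \code{fs}, \code{labels}
#'   (\code{sleep_labels} per second), \code{epochs}
#' @export
generate_state_session <- function(epochs, seed = 1L, fs = 1000,
                                   emg_sd = c(wake = 30, NREM = 6, REM = 4)) {
  stopifnot(all(epochs$state %in% c("wake", "NREM", "REM")),
            all(epochs$duration_s > 0))
  set.seed(seed)
  total <- sum(epochs$duration_s)
  n <- round(total * fs)
  eeg <- shaped_noise(n, fs, exponent = 1, sd = 20)
  emg <- shaped_noise(n, fs, exponent = 0, sd = 1)
  tt <- (seq_len(n) - 1) / fs
  t0 <- 0
  lab <- character(ceiling(total))
  emg_scale <- numeric(n)
  for (i in seq_len(nrow(epochs))) {
    st <- epochs$state[i]; d <- epochs$duration_s[i]
    sel <- tt >= t0 & tt < t0 + d
    m <- sum(sel)
    if (st == "NREM") {
      ph <- cumsum(2 * pi * stats::runif(m, 1, 3) / fs)
      eeg[sel] <- eeg[sel] + 120 * cos(ph)
      ## spindle transients (9-15 Hz, ~0.7 s) every few seconds
      nsp <- max(1, round(d / 5))
      for (s0 in stats::runif(nsp, t0, max(t0, t0 + d - 1))) {
        i0 <- round(s0 * fs); k <- round(0.7 * fs)
        ii <- i0 + seq_len(k)
        ii <- ii[ii <= n]
        w <- exp(-((seq_along(ii) - k / 2)^2) / (2 * (k / 6)^2))
        eeg[ii] <- eeg[ii] + 25 * w * cos(2 * pi * 12 * seq_along(ii) / fs)
      }
    } else {
      ph <- cumsum(2 * pi * stats::runif(m, 6, 9) / fs)
      eeg[sel] <- eeg[sel] + 40 * cos(ph)
    }
    emg_scale[sel] <- emg_sd[[st]]
    lab[(floor(t0) + 1):min(ceiling(t0 + d), length(lab))] <- st
    t0 <- t0 + d
  }
  emg <- emg * emg_scale
  labels <- data.frame(second = seq_len(ceiling(total)) - 1L, state = lab)
  class(labels) <- c("sleep_labels", "data.frame")
  list(eeg = eeg, emg = emg, fs = fs, labels = labels, epochs = epochs)
}

#' Simulate a full recording session with ground truth
#'
#' Presets bundle the generator settings of the main study conditions:
#' \describe{
#'   \item{awake-stim}{awake baseline; 30 s laser trials induce local
#'     slow waves (default +2.5 dB delta on "affected" channels),
#'     phase-locked units with OFF periods at troughs.}
#'   \item{nrem}{sleeping animal; trials further increase delta and
#'     suppress spindle power.}
#'   \item{anesthesia}{continuous global slow waves, no laser-locked
#'     delta change.}
#'   \item{halo}{NREM baseline; trials *reduce* delta power (inhibitory
#'     opsin).}
#' }
#'
#' @param preset one of awake-stim, nrem, anesthesia, halo
#' @param duration_s record length (s)
#' @param n_trials laser trial count
#' @param n_channels LFP channel count
#' @param n_affected channels receiving the delta effect
#' @param delta_effect_db effect on affected channels (dB)
#' @param n_units spike-train count (on channel 1's slow wave)
#' @param kappa_on phase-locking concentration during laser-ON
#' @param stim_s trial duration (s)
#' @param seed integer seed
#' @return \code{session} with attribute \code{ground_truth}
#' @export
simulate_session <- function(preset = c("awake-stim", "nrem", "anesthesia",
                                        "halo"),
                             duration_s = 600, n_trials = 6, n_channels = 2,
                             n_affected = 1, delta_effect_db = NULL,
                             n_units = 2, kappa_on = 1.5, stim_s = 30,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(delta_effect_db))
    delta_effect_db <- switch(preset, "awake-stim" = 2.5, "nrem" = 0.6,
                              "anesthesia" = 0, "halo" = -0.8)
  fs <- 1000
  gap_lo <- 60; gap_hi <- 90
  set.seed(derive_seed(seed, "trials"))
  need <- 30 + n_trials * (stim_s + gap_hi)
  if (duration_s < need)
    duration_s <- need
  onsets <- 30 + cumsum(c(0, stats::runif(n_trials - 1, gap_lo, gap_hi) + stim_s))
  trials <- trial_set(onsets, onsets + stim_s, 1)
  lfp <- matrix(0, n_channels, round(duration_s * fs))
  gts <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    eff <- if (ch <= n_affected) delta_effect_db else 0
    g <- generate_lfp(duration_s, trials, delta_effect_db = eff,
                      seed = derive_seed(seed, paste0("lfp", ch)), fs = fs)
    lfp[ch, ] <- g$trace
    gts[[ch]] <- g$ground_truth
  }
  theta <- gts[[1]]$theta
  tt <- (seq_len(ncol(lfp)) - 1) / fs
  on_mask <- rep(FALSE, ncol(lfp))
  for (i in seq_along(trials$onsets))
    on_mask[tt %inwin% c(trials$onsets[i], trials$offsets[i])] <- TRUE
  offs <- place_off_periods(gts[[1]]$trough_times,
                            seed = derive_seed(seed, "offs"))
  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    spikes[[u]] <- generate_spike_train(
      duration_s, base_rate_hz = 8, kappa = kappa_on, phi0 = pi,
      theta = theta, fs_phase = fs, mod_mask = on_mask,
      off_periods = offs, seed = derive_seed(seed, paste0("unit", u)),
      unit_id = u, peak_to_trough_us = if (u %% 2) 300 else 150)
  }
  st <- switch(preset,
    "awake-stim" = data.frame(state = "wake", duration_s = duration_s),
    "anesthesia" = data.frame(state = "NREM", duration_s = duration_s),
    data.frame(state = c("wake", "NREM"),
               duration_s = c(20, duration_s - 20)))
  ss <- generate_state_session(st, seed = derive_seed(seed, "state"), fs = fs)
  s <- session(lfp, fs, eeg = ss$eeg, emg = ss$emg, fs_eeg = fs, fs_emg = fs,
               spikes = spikes, trials = trials,
               state_labels = ss$labels, name = paste0("synthetic-", preset))
  attr(s, "ground_truth") <- list(preset = preset, lfp = gts,
                                  off_periods = offs,
                                  kappa_on = kappa_on, phi0 = pi,
                                  state = ss$epochs)
  s
}
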