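## Population OFF-period detection and the gamma-renewal null.
##
## "Firing rate of zero" is defined through a Gaussian kernel (SD
## kernel_sd_ms, truncated at +/- 4 SD): the smoothed rate is zero
## exactly where no spike falls within the truncated support, so OFF
## periods are computed by exact interval arithmetic on the spike gaps --
## a gap g between consecutive spikes contributes an OFF period of
## length g - 2 * (4 * kernel_sd) when that remainder reaches min_dur.

#' Detect population OFF periods from pooled spike times
#'
#' @param spike_times_pooled sorted pooled spike times (s); single- and
#'   multi-unit events together
#' @param t0,t1 observation window (s)
#' @param kernel_sd_ms Gaussian rate-kernel SD (ms)
#' @param min_dur_ms minimum OFF duration (ms)
#' @param include_edges count silent stretches at the record edges as OFF
#'   periods (default TRUE)
#' @return data.frame of class \code{off_periods}: start_s, end_s,
#'   duration_ms
#' @export
detect_off_periods <- function(spike_times_pooled, t0, t1,
                               kernel_sd_ms = 20, min_dur_ms = 50,
                               include_edges = TRUE) {
  if (t1 <= t0) stop("t1 must exceed t0")
  s <- sort(spike_times_pooled[spike_times_pooled >= t0 &
                               spike_times_pooled < t1])
  w <- 4 * kernel_sd_ms / 1000
  if (!length(s)) {
    if (include_edges && (t1 - t0) * 1000 >= min_dur_ms) {
      out <- data.frame(start_s = t0, end_s = t1,
                        duration_ms = (t1 - t0) * 1000)
    } else out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                             duration_ms = numeric(0))
    class(out) <- c("off_periods", "data.frame")
    return(out)
  }
  starts <- c(if (include_edges) t0, s + w)
  ends <- c(if (include_edges) s[1] - w, s[-1] - w, if (include_edges) t1)
  if (!include_edges) { starts <- s[-length(s)] + w; ends <- s[-1] - w }
  starts <- pmax(starts, t0); ends <- pmin(ends, t1)
  dur <- (ends - starts) * 1000
  keep <- dur >= min_dur_ms
  out <- data.frame(start_s = starts[keep], end_s = ends[keep],
                    duration_ms = dur[keep])
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("off_periods", "data.frame")
  out
}

#' Kernel-smoothed instantaneous population rate
#'
#' Gaussian kernel (SD \code{kernel_sd_ms}, truncated at +/- 4 SD) on a
#' 1 ms grid; the same rate definition underlying
#' \code{\link{detect_off_periods}}.
#'
#' @param spike_times spike times (s)
#' @param t0,t1 window (s)
#' @param kernel_sd_ms kernel SD (ms)
#' @param dt_ms grid step (ms)
#' @return list with \code{time_s} and \code{rate_hz}
#' @export
smoothed_rate <- function(spike_times, t0, t1, kernel_sd_ms = 20, dt_ms = 1) {
  dt <- dt_ms / 1000
  grid <- seq(t0, t1, by = dt)
  counts <- tabulate(findInterval(
    spike_times[spike_times >= t0 & spike_times < t1], grid),
    length(grid))
  sm <- gaussian_smooth(counts, kernel_sd_ms / dt_ms)
  list(time_s = grid, rate_hz = sm / dt)
}

## percent of [t0, t1) spent inside OFF periods
off_fraction <- function(spike_times, t0, t1, ...) {
  op <- detect_off_periods(spike_times, t0, t1, ...)
  100 * sum(op$duration_ms) / 1000 / (t1 - t0)
}

#' Gamma-renewal null for the fraction of time in OFF periods
#'
#' Fits a gamma distribution to the observed interspike intervals (MLE,
#' method-of-moments fallback) and simulates \code{n_sims} renewal trains
#' with the same spike count over the same window, applying the OFF
#' detector identically to each. Reports the observed OFF fraction and
#' the null mean with its 2.5th/97.5th percentiles, all in percent.
#'
#' @param spike_times spike times (s)
#' @param t0,t1 observation window (s)
#' @param n_sims simulations (default 1000)
#' @param seed integer seed
#' @param kernel_sd_ms,min_dur_ms OFF-detector settings
#' @return \code{off_null_result}: \code{observed}, \code{null_mean},
#'   \code{null_ci}, \code{null_fractions}, \code{shape}, \code{rate},
#'   \code{n_sims}
#' @export
off_fraction_null <- function(spike_times, t0, t1, n_sims = 1000, seed = 1L,
                              kernel_sd_ms = 20, min_dur_ms = 50) {
  s <- sort(spike_times[spike_times >= t0 & spike_times < t1])
  if (length(s) < 2) stop("need at least 2 spikes")
  isi <- diff(s)
  if (length(isi) < 100)
    warning("fewer than 100 ISIs; gamma fit may be unstable")
  fit <- tryCatch(
    MASS::fitdistr(isi, "gamma", lower = c(1e-6, 1e-6)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    shape <- unname(fit$estimate["shape"]); rate <- unname(fit$estimate["rate"])
  } else {
    m <- mean(isi); v <- stats::var(isi)
    shape <- m^2 / v; rate <- m / v
  }
  obs <- off_fraction(s, t0, t1, kernel_sd_ms = kernel_sd_ms,
                      min_dur_ms = min_dur_ms)
  n <- length(s)
  set.seed(seed)
  nulls <- replicate(n_sims, {
    tr <- t0 + cumsum(stats::rgamma(n, shape, rate))
    off_fraction(tr, t0, t1, kernel_sd_ms = kernel_sd_ms,
                 min_dur_ms = min_dur_ms)
  })
  structure(list(observed = obs, null_mean = mean(nulls),
                 null_ci = unname(stats::quantile(nulls, c(0.025, 0.975))),
                 null_fractions = nulls, shape = shape, rate = rate,
                 n_sims = n_sims),
            class = "off_null_result")
}

#' Paired change in OFF fraction across laser trials
#'
#' Percent of time in OFF periods during each trial's stimulation window
#' versus its pre-stimulus window, summarised by signed-rank inversion.
#'
#' @param spike_times pooled spike times (s)
#' @param trials \code{\link{trial_set}}
#' @param pre_s baseline window length (s)
#' @param ... passed to \code{\link{detect_off_periods}}
#' @return list with \code{effect} and per-trial \code{frac_pre},
#'   \code{frac_on} (percent)
#' @export
off_fraction_change <- function(spike_times, trials, pre_s = 30, ...) {
  nt <- length(trials$onsets)
  if (nt < 6) stop("need at least 6 trials")
  frac_pre <- frac_on <- numeric(nt)
  for (i in seq_len(nt)) {
    on <- trials$onsets[i]; off <- trials$offsets[i]
    frac_pre[i] <- off_fraction(spike_times, on - pre_s, on, ...)
    frac_on[i] <- off_fraction(spike_times, on, off, ...)
  }
  list(effect = signed_rank_effect(frac_on - frac_pre),
       frac_pre = frac_pre, frac_on = frac_on)
}

#' Chi-square test of OFF-period phase uniformity
#'
#' Each OFF period's midpoint is assigned a delta phase; midpoint phases
#' are split into \code{n_bins} bins and tested against uniformity with
#' Pearson's chi-square (dof = n_bins - 1).
#'
#' @param offs \code{off_periods}
#' @param phase \code{phase_series} (from \code{\link{delta_phase}})
#' @param n_bins phase bins (default 10)
#' @return list: \code{statistic}, \code{dof}, \code{p}, \code{counts},
#'   \code{phases}
#' @export
off_phase_test <- function(offs, phase, n_bins = 10) {
  if (nrow(offs) < 20) stop("need at least 20 OFF periods")
  mid <- (offs$start_s + offs$end_s) / 2
  ph <- phase_at(phase, mid)
  ph <- ph[is.finite(ph)]
  counts <- tabulate(phase_bin(ph, n_bins), n_bins)
  res <- chi_square_uniformity(counts)
  c(res, list(counts = counts, phases = ph))
}
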