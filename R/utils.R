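## Shared signal-processing primitives and seed plumbing.

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each stochastic stage of the pipeline draws its own seed by stable
#' hashing of the stage name, so adding or reordering stages never
#' perturbs another stage's random stream.
#'
#' @param seed global integer seed
#' @param stage character stage name
#' @return an integer seed in [0, 2^31 - 1)
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483629
  as.integer((seed %% 2147483629 + h) %% 2147483629)
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR designed with
#' \code{signal::fir1}, applied by FFT convolution with the group delay
#' removed, which is exactly zero-phase for a symmetric filter. Edges are
#' reflection-padded by the filter half-length. The default order is
#' \code{3 * fs / f_lo}, capped at a third of the record length.
#'
#' @param x numeric trace
#' @param fs sampling rate (Hz)
#' @param lo,hi band edges (Hz); \code{lo = 0} gives a lowpass
#' @param order filter order (taps - 1); even; default \code{3*fs/lo}
#' @return filtered trace, same length as \code{x}
#' @export
fir_bandpass <- function(x, fs, lo, hi, order = NULL) {
  n <- length(x)
  if (hi >= fs / 2) stop("upper band edge must be below Nyquist")
  if (is.null(order)) order <- if (lo > 0) 3 * fs / lo else 3 * fs / hi
  order <- min(order, floor((n - 1) / 3))
  order <- 2L * max(2L, floor(order / 2))  # even -> odd tap count, exact delay
  h <- if (lo > 0) {
    signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  } else {
    signal::fir1(order, hi / (fs / 2), type = "low")
  }
  half <- order / 2L
  xp <- c(rev(x[seq_len(min(half, n - 1)) + 1L]), x,
          rev(x[n - seq_len(min(half, n - 1))]))
  npad <- (length(xp) - n - 2 * min(half, n - 1))  # zero; kept for clarity
  y <- fftconv(xp, as.numeric(h))
  pre <- min(half, n - 1)
  y[(pre + half + 1L):(pre + half + n)]
}

## linear convolution via FFT (full length n + m - 1)
fftconv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Analytic signal via the FFT
#'
#' @param x real numeric trace
#' @return complex analytic signal; \code{Arg()} gives instantaneous
#'   phase, \code{Mod()} the envelope
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' for the given time-bandwidth product. For window lengths above 2048
#' samples the tapers are computed at 2048 points and spline-interpolated
#' to full length, then re-normalised to unit energy.
#'
#' @param n window length in samples
#' @param nw time-bandwidth product
#' @param k number of tapers (k <= 2*nw - 1 recommended)
#' @return n x k matrix, columns unit-energy tapers
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1) stop("taper count K must be >= 1")
  if (n < 8) stop("window too short for taper computation")
  nb <- min(n, 1024L)
  V <- dpss_base(nb, nw, k)
  if (nb < n) {
    Vf <- apply(V, 2, function(v)
      stats::spline(x = seq(0, 1, length.out = nb), y = v,
                    xout = seq(0, 1, length.out = n))$y)
    V <- sweep(Vf, 2, sqrt(colSums(Vf^2)), "/")
  }
  V
}

.dpss_base_cache <- new.env(parent = emptyenv())

## exact tapers at length nb via the symmetric tridiagonal eigenproblem
dpss_base <- function(nb, nw, k) {
  key <- paste(nb, nw, k, sep = "_")
  got <- .dpss_base_cache[[key]]
  if (!is.null(got)) return(got)
  w <- nw / nb
  t <- 0:(nb - 1)
  dg <- ((nb - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- (1:(nb - 1)) * ((nb - 1):1) / 2
  A <- matrix(0, nb, nb)
  diag(A) <- dg
  A[cbind(1:(nb - 1), 2:nb)] <- od
  A[cbind(2:nb, 1:(nb - 1))] <- od
  V <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  ## polarity convention: symmetric tapers positive mean, antisymmetric
  ## positive initial slope
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) { if (s < 0) V[, j] <- -V[, j] }
    else if (V[2, j] - V[1, j] < 0) V[, j] <- -V[, j]
  }
  .dpss_base_cache[[key]] <- V
  V
}

#' Gaussian smoothing of a regularly sampled series
#'
#' Kernel truncated at +/- 4 SD, normalised to unit sum, applied by FFT
#' convolution with reflection padding.
#'
#' @param x numeric series
#' @param sd_samples kernel standard deviation in samples
#' @return smoothed series, same length
#' @export
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  kk <- stats::dnorm(-half:half, sd = sd_samples)
  kk <- kk / sum(kk)
  n <- length(x)
  p <- min(half, n - 1)
  xp <- c(rev(x[seq_len(p) + 1L]), x, rev(x[n - seq_len(p)]))
  y <- fftconv(xp, kk)
  y[(p + half + 1L):(p + half + n)]
}

## simple moving average with window w samples (centred, reflection-padded)
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  gaussianless <- rep(1 / w, w)
  n <- length(x)
  half <- floor(w / 2)
  p <- min(half, n - 1)
  xp <- c(rev(x[seq_len(p) + 1L]), x, rev(x[n - seq_len(p)]))
  y <- fftconv(xp, gaussianless)
  y[(p + floor((w - 1) / 2) + 1L):(p + floor((w - 1) / 2) + n)]
}

## half-open interval membership [a, b)
`%inwin%` <- function(t, win) t >= win[1] & t < win[2]

## wrap angles to [-pi, pi)
wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi
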