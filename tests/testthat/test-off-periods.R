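test_that("OFF detection: degenerate, dense, and hand-constructed-gap inputs", {
  # no spikes: the whole window is one OFF period
  op <- detect_off_periods(numeric(0), 0, 10)
  expect_equal(nrow(op), 1)
  expect_equal(op$duration_ms, 10000)

  # regular 100 Hz spiking: no OFF periods
  op2 <- detect_off_periods(seq(0, 60, by = 0.01), 0, 60)
  expect_equal(nrow(op2), 0)

  # single 200 ms gap: duration = gap - 2 * truncation half-width
  sp <- sort(c(seq(0, 4.9, by = 0.005), seq(5.1, 10, by = 0.005)))
  op3 <- detect_off_periods(sp, 0, 10, kernel_sd_ms = 10)
  expect_equal(nrow(op3), 1)
  expect_equal(op3$duration_ms, 200 - 2 * 4 * 10, tolerance = 2 / 120)
  expect_error(detect_off_periods(sp, 5, 5), "exceed")
})

test_that("OFF fraction is monotone in the kernel width and matches a gap census", {
  set.seed(12)
  sp <- sort(runif(1500, 0, 100))  # ~15 Hz Poisson
  f <- vapply(c(5, 10, 20, 30), function(k)
    localsleep:::off_fraction(sp, 0, 100, kernel_sd_ms = k), numeric(1))
  expect_true(all(diff(f) <= 1e-9))

  # brute-force gap census oracle at kernel_sd 10
  w <- 4 * 10 / 1000
  gaps <- diff(c(0 - w, sp, 100 + w))  # edge-inclusive
  durs <- (gaps - 2 * w)
  durs <- durs[durs >= 0.05]
  expect_equal(localsleep:::off_fraction(sp, 0, 100, kernel_sd_ms = 10),
               100 * sum(durs) / 100, tolerance = 1e-9)
})

test_that("smoothed rate is zero exactly where the detector says OFF", {
  sp <- sort(c(seq(0, 4.9, by = 0.02), seq(5.3, 10, by = 0.02)))
  op <- detect_off_periods(sp, 0, 10)
  sr <- smoothed_rate(sp, 0, 10)
  inside <- sr$time_s > op$start_s[1] & sr$time_s < op$end_s[1]
  expect_true(all(sr$rate_hz[inside] < 1e-6))
  expect_gt(max(sr$rate_hz), 10)
})

test_that("gamma-renewal null is self-consistent and detects injected silences", {
  set.seed(13)
  # injected OFF periods (~13% of the record) push the observed fraction
  # beyond the null's 97.5th percentile
  offs <- data.frame(start_s = seq(5, 595, by = 5),
                     end_s = seq(5, 595, by = 5) + 0.65)
  tr <- generate_spike_train(600, 15, off_periods = offs, seed = 4)
  r <- off_fraction_null(tr$spike_times, 0, 600, n_sims = 300, seed = 1)
  expect_gt(r$observed, r$null_ci[2])
  expect_equal(length(r$null_fractions), 300)
  expect_true(all(r$null_fractions >= 0 & r$null_fractions <= 100))

  # Poisson train: observed inside the null interval most of the time
  inside <- replicate(15, {
    sp <- generate_spike_train(100, 20, seed = sample.int(1e6, 1))
    rn <- off_fraction_null(sp$spike_times, 0, 100, n_sims = 200,
                            seed = sample.int(1e6, 1))
    rn$observed >= rn$null_ci[1] && rn$observed <= rn$null_ci[2]
  })
  expect_gte(mean(inside), 0.8)
  expect_error(off_fraction_null(c(1), 0, 10), "at least 2")
})

test_that("phase uniformity test: even spread, single bin, and calibration", {
  fs <- 1000
  ph <- structure(list(phase = rep(seq(-pi, pi - 1e-9, length.out = fs * 10),
                                   length.out = fs * 10),
                       valid = rep(TRUE, fs * 10), fs = fs, band = c(1, 4)),
                  class = "phase_series")
  # one OFF midpoint per bin -> chi-square 0
  mids <- seq(0.5, 9.5, by = 1)
  centers <- ph$phase[floor(mids * fs) + 1]
  offs <- data.frame(start_s = mids - 0.01, end_s = mids + 0.01,
                     duration_ms = 20)
  offs <- offs[rep(1:10, 2), ]  # >= 20 OFF periods
  r <- off_phase_test(offs, ph)
  expect_equal(r$statistic, 0)
  expect_equal(r$dof, 9)

  # all midpoints in one bin: chi-square = 9n
  offs2 <- data.frame(start_s = rep(0.09, 50), end_s = rep(0.11, 50))
  r2 <- off_phase_test(offs2, ph)
  expect_equal(r2$statistic, 9 * 50)
  expect_lt(r2$p, 1e-6)
})
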