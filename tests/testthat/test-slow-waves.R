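test_that("detector honours thresholds, DC offsets, and the closed-form count", {
  fs <- 1000
  expect_equal(nrow(detect_slow_waves(rep(0, fs * 60), fs)), 0)

  x <- 400 * sin(2 * pi * 2 * seq(0, 300 - 1 / fs, 1 / fs))
  ev <- detect_slow_waves(x, fs)
  expect_equal(nrow(ev), ceiling(0.03 * 600))
  expect_equal(median(ev$p2p_uv), 800, tolerance = 0.01)
  expect_true(all(ev$trough_uv < -100))
  expect_true(all(ev$peak_time_s > ev$trough_time_s))
  expect_true(all(abs(ev$p2p_uv - (ev$peak_uv - ev$trough_uv)) < 1e-9))

  # DC offset leaves the detection unchanged (bandpass removes it)
  ev2 <- detect_slow_waves(x + 5000, fs)
  expect_equal(ev2$trough_time_s, ev$trough_time_s)

  # amplitudes scale with the trace
  ev3 <- detect_slow_waves(2 * x, fs)
  expect_equal(ev3$p2p_uv, 2 * ev$p2p_uv, tolerance = 1e-9)

  # sub-threshold minima yield nothing
  expect_equal(nrow(detect_slow_waves(x / 8, fs)), 0)
  expect_error(detect_slow_waves(x, fs = 8), "sampling rate")
})

test_that("artifact windows are excluded before percentile ranking", {
  fs <- 1000
  x <- 400 * sin(2 * pi * 2 * seq(0, 120 - 1 / fs, 1 / fs))
  bad_t <- c(30, 70)
  for (b in bad_t) {
    i <- (b * fs):(b * fs + 400)
    x[i] <- x[i] + rep_len(c(3000, -3000), length(i))
  }
  ev <- detect_slow_waves(x, fs)
  for (b in bad_t)
    expect_false(any(ev$trough_time_s >= b & ev$trough_time_s <= b + 0.4))
})

test_that("generator troughs are recovered with high precision and recall", {
  # strong injection so the waves clear the detector's -100 uV floor
  tr <- make_trials(20, gap_s = 90)
  g <- generate_lfp(max(tr$offsets) + 40, tr, delta_effect_db = 14, seed = 3)
  ev <- detect_slow_waves(g$trace, g$fs, top_pct = 100)
  truth <- g$ground_truth$trough_times
  hit <- vapply(truth, function(t0)
    any(abs(ev$trough_time_s - t0) <= 0.1), logical(1))
  expect_gte(mean(hit), 0.9)
  on <- vapply(ev$trough_time_s, function(t)
    any(t >= tr$onsets & t < tr$offsets), logical(1))
  prec <- vapply(ev$trough_time_s[on], function(t)
    any(abs(truth - t) <= 0.1), logical(1))
  expect_gte(mean(prec), 0.9)
})

test_that("event rate change is null for uniform events and rate-normalised", {
  tr <- make_trials(10, stim_s = 10, gap_s = 20, t0 = 15)
  ev <- data.frame(trough_time_s = seq(1, max(tr$offsets) + 10, by = 0.9))
  rc <- event_rate_change(ev, tr, pre_s = 10)
  expect_lt(abs(rc$effect$median), 0.15)
  expect_true(rc$effect$ci[1] <= 0 && rc$effect$ci[2] >= 0)

  # ON-only events appear as a positive rate difference
  ev_on <- data.frame(trough_time_s = unlist(lapply(seq_along(tr$onsets),
    function(i) seq(tr$onsets[i] + 0.1, tr$offsets[i] - 0.1, length.out = 3))))
  rc2 <- event_rate_change(ev_on, tr, pre_s = 10)
  expect_equal(rc2$effect$median, 0.3, tolerance = 0.05)
})

test_that("amplitude statistics shift with the asymmetry of the input", {
  set.seed(9)
  a <- data.frame(trough_uv = rnorm(200, -350, 20), peak_uv = rnorm(200, 180, 20))
  b <- data.frame(trough_uv = rnorm(200, -250, 20), peak_uv = rnorm(200, 120, 20))
  st <- event_amplitude_stats(a, b, seed = 2)
  expect_lt(st$trough_change$median, 0)   # deeper troughs
  expect_gt(st$peak_change$median, 0)     # larger peaks
  expect_lt(st$trough_change$ci[2], 0)
  same <- event_amplitude_stats(a, a, seed = 3)
  expect_lt(abs(same$trough_change$median), 10)
  expect_error(event_amplitude_stats(a[0, ], b), "non-empty|events")
})
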