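test_that("waveform classification is a pure threshold with a documented boundary", {
  expect_equal(as.character(classify_unit(150)), "Narrow")
  expect_equal(as.character(classify_unit(250)), "Wide")
  expect_equal(as.character(classify_unit(200)), "Wide")
  expect_equal(as.character(classify_unit(c(199.9, 200, 300))),
               c("Narrow", "Wide", "Wide"))
  expect_error(classify_unit(0), "positive")
})

test_that("rate change: null unit spans zero, suppressed unit is detected", {
  tr <- make_trials(12, stim_s = 10, gap_s = 20, t0 = 15)
  dur <- max(tr$offsets) + 15
  sp <- generate_spike_train(dur, 12, seed = 31)
  rc <- rate_change(sp$spike_times, tr, pre_s = 10)
  expect_true(rc$effect$ci[1] <= 0 && rc$effect$ci[2] >= 0)
  expect_false(rc$significant)

  # 50% ON drop via forced silences covering half of each ON window
  offs <- do.call(rbind, lapply(seq_along(tr$onsets), function(i)
    data.frame(start_s = tr$onsets[i] + seq(0, 9, by = 1),
               end_s = tr$onsets[i] + seq(0.5, 9.5, by = 1))))
  spd <- generate_spike_train(dur, 12, off_periods = offs, seed = 32)
  rcd <- rate_change(spd$spike_times, tr, pre_s = 10)
  expect_lt(rcd$effect$median, 0)
  expect_lt(rcd$effect$ci[2], 0)
  expect_true(rcd$significant)
})

test_that("onset latency finds a fast rate drop and stays quiet on null data", {
  set.seed(33)
  onsets <- 30 + (0:39) * 70
  dur <- max(onsets) + 40
  st <- sort(runif(20 * dur, 0, dur))
  keep <- vapply(st, function(t) {
    rel <- t - onsets
    !any(rel >= 0 & rel < 30) || runif(1) < 0.1
  }, logical(1))
  ol <- onset_latency(st[keep], onsets, "rate", seed = 1)
  expect_lte(ol$first_significant_ms, 30)

  # scaling the baseline rate does not change the detection
  ol2 <- onset_latency(rep(st[keep], 2) + rep(c(0, 1e-7), each = sum(keep)),
                       onsets, "rate", seed = 1)
  expect_equal(ol2$first_significant_ms, ol$first_significant_ms)

  hits <- vapply(1:25, function(i) {
    set.seed(400 + i)
    stn <- sort(runif(20 * dur, 0, dur))
    o <- onset_latency(stn, onsets, "rate", seed = i, n_boot = 300)
    !is.na(o$first_significant_ms)
  }, logical(1))
  expect_lte(mean(hits), 0.08)
})

test_that("history GLM recovers facilitation and refractoriness", {
  hg <- rep(1, 10); hg[2] <- 3
  tr <- generate_spike_train(120, 10, history_gain = hg, seed = 6)
  f <- fit_history_glm(tr$spike_times, matrix(c(0, 120), 1))
  expect_true(f$converged)
  expect_equal(nrow(f$coef), 50)
  expect_gt(f$coef$ci_lo[2], 0)  # (2, 4] ms facilitation

  hr <- rep(1, 10); hr[1] <- 1e-6; hr[2] <- 1e-6; hr[3] <- 0.3
  trr <- generate_spike_train(120, 12, history_gain = hr, seed = 7)
  fr <- fit_history_glm(trr$spike_times, matrix(c(0, 120), 1))
  expect_lt(fr$coef$estimate[1], 0)
  expect_lt(fr$coef$estimate[2], 0)
  expect_error(fit_history_glm(tr$spike_times[1:100], matrix(c(0, 120), 1)),
               "fewer than")
})

test_that("2-4 ms condition comparison flags a switched-on facilitation only", {
  hg <- rep(1, 10); hg[2] <- 3
  spb <- generate_spike_train(120, 10, seed = 8)
  sps <- generate_spike_train(120, 10, history_gain = hg, seed = 9)
  fb <- fit_history_glm(spb$spike_times, matrix(c(0, 120), 1),
                        condition = "baseline")
  fs <- fit_history_glm(sps$spike_times, matrix(c(0, 120), 1),
                        condition = "stim")
  cmp <- compare_history_2_4ms(fb, fs)
  expect_true(cmp$changed)
  expect_equal(cmp$direction, 1)

  cmp0 <- compare_history_2_4ms(fb, fb)
  expect_false(cmp0$changed)
})
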