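test_that("multitaper spectrum concentrates a tone and conserves variance", {
  fs <- 200
  x <- tone(3, 30, fs)
  sp <- multitaper_spectrum(x, fs, window_s = 10, k = 5, nw = 3)
  inband <- sp$freqs >= 3 - 2 * 3 / 10 & sp$freqs <= 3 + 2 * 3 / 10
  expect_gte(sum(sp$power[inband]) / sum(sp$power), 0.95)

  # Parseval over 10 white-noise realisations
  set.seed(5)
  rel <- replicate(10, {
    y <- rnorm(fs * 60, sd = 2)
    spy <- multitaper_spectrum(y, fs, 10, 5)
    sum(spy$power) * (spy$freqs[2] - spy$freqs[1]) / var(y)
  })
  expect_lt(abs(mean(rel) - 1), 0.05)

  # constant signal: all power inside the taper bandwidth around 0 Hz
  spc <- multitaper_spectrum(rep(3, fs * 10), fs, 5, 3)
  expect_gt(spc$power[1], 0)
  dc <- spc$freqs <= 2 / 5  # NW / window_s
  expect_gt(sum(spc$power[dc]) / sum(spc$power), 0.99)

  expect_error(multitaper_spectrum(x, fs, 10, 0), "K must be")
  expect_error(multitaper_spectrum(x[1:100], fs, 10, 5), "shorter")
})

test_that("band power is additive and dB change is scale invariant", {
  set.seed(6)
  fs <- 250
  x <- rnorm(fs * 60)
  sp <- multitaper_spectrum(x, fs, 10, 5)
  df <- sp$freqs[2] - sp$freqs[1]
  a <- band_power(sp, c(1, 10 - df))
  b <- band_power(sp, c(10, 40))
  expect_equal(a + b, band_power(sp, c(1, 40)), tolerance = 1e-10)

  tr <- make_trials(8, stim_s = 10, gap_s = 20, t0 = 15)
  y <- rnorm(fs * (max(tr$offsets) + 15))
  e1 <- band_power_change(y, fs, tr, c(1, 4), pre_s = 10)
  e2 <- band_power_change(7.7 * y, fs, tr, c(1, 4), pre_s = 10)
  expect_equal(e1$median_db, e2$median_db, tolerance = 1e-9)
  expect_true(e1$ci_db[1] <= 0 && e1$ci_db[2] >= 0)
})

test_that("normalized spectrogram is ~0 dB on stationary noise and exact for one trial", {
  set.seed(7)
  fs <- 200
  tr <- make_trials(20, stim_s = 10, gap_s = 15, t0 = 15)
  x <- rnorm(fs * (max(tr$offsets) + 15))
  sg <- normalized_spectrogram(x, fs, tr, window_s = 5, k = 5, pre_s = 10,
                               post_s = 10)
  cells <- sg$db[, sg$freqs >= 1 & sg$freqs <= 50]
  expect_lt(abs(mean(cells)), 0.3)
  expect_lt(quantile(abs(cells), 0.95), 1.2)

  one <- trial_set(tr$onsets[1], tr$offsets[1])
  sg1 <- normalized_spectrogram(x, fs, one, window_s = 5, k = 5, pre_s = 10,
                                post_s = 10)
  expect_equal(sg1$n_trials, 1)
  # median of one trial = that trial itself: the per-frequency baseline
  # mean of the linear ratio is exactly 1
  basel <- sg1$time_s < 0
  expect_equal(colMeans(10^(sg1$db[basel, , drop = FALSE] / 10)),
               rep(1, length(sg1$freqs)), tolerance = 1e-8)
})

test_that("injected delta effect is recovered within +/- 0.5 dB", {
  fx <- lfp_injected()
  eff <- band_power_change(fx$g$trace, fx$g$fs, fx$trials, c(1, 4))
  expect_lt(abs(eff$median_db - 2.5), 0.5)
  expect_gt(eff$ci_db[1], 0)
  sg <- normalized_spectrogram(fx$g$trace, fx$g$fs, fx$trials)
  cell <- mean(sg$db[sg$time_s > 2.5, sg$freqs >= 1 & sg$freqs <= 4])
  expect_gt(cell, 1.5)
  expect_lt(cell, 3.5)
})

test_that("delta-effect map flags injected channels and spares null ones", {
  fs <- 1000
  tr <- make_trials(12)
  dur <- max(tr$offsets) + 40
  inj <- generate_lfp(dur, tr, delta_effect_db = 2.5, seed = 41, fs = fs)
  nul <- generate_lfp(dur, tr, delta_effect_db = 0, seed = 42, fs = fs)
  lfp <- rbind(inj$trace, nul$trace)
  map <- delta_effect_map(lfp, fs, tr)
  expect_true(map$significant_a[1])
  expect_false(map$significant_a[2])
  expect_true(map$significant_b[1])
  expect_gt(map$change_db[1], 1.5)
})
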