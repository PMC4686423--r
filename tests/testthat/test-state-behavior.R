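test_that("EMG band power scales quadratically and detects an ON drop", {
  set.seed(41)
  fs <- 1000
  tr <- make_trials(10, stim_s = 10, gap_s = 20, t0 = 15)
  dur <- max(tr$offsets) + 15
  n <- dur * fs
  emg <- rnorm(n)
  bp1 <- emg_band_power(emg, fs)
  bp2 <- emg_band_power(2 * emg, fs)
  expect_equal(bp2$power, 4 * bp1$power, tolerance = 1e-9)
  expect_error(emg_band_power(emg, 300), "400")

  # stationary: no effect
  e0 <- emg_power_change(emg, fs, tr, pre_s = 10)
  expect_true(e0$effect$ci[1] <= 0 && e0$effect$ci[2] >= 0)

  # amplitude halved during ON: negative change, visible in second one
  scal <- rep(1, n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_along(tr$onsets))
    scal[tt >= tr$onsets[i] & tt < tr$offsets[i]] <- 0.5
  e1 <- emg_power_change(emg * scal, fs, tr, pre_s = 10)
  expect_lt(e1$effect$median, 0)
  expect_lt(e1$effect$ci[2], 0)
  expect_lt(e1$onset_effect$median, 0)
})

test_that("sleep scorer recovers generator states and honours its thresholds", {
  ep <- data.frame(state = c("wake", "NREM", "wake", "NREM", "REM"),
                   duration_s = c(60, 80, 40, 60, 25))
  ss <- generate_state_session(ep, seed = 2)
  lab <- score_sleep(ss$eeg, ss$emg, ss$fs)
  acc <- mean(ss$labels$state == lab$state[seq_len(nrow(ss$labels))])
  expect_gte(acc, 0.9)

  # wake-only with the generator's documented EMG scale
  ssw <- generate_state_session(data.frame(state = "wake", duration_s = 120),
                                seed = 3)
  labw <- score_sleep(ssw$eeg, ssw$emg, ssw$fs, emg_thresh = 15)
  expect_gte(mean(labw$state == "wake"), 0.95)

  # EMG everywhere above threshold: 100% wake
  lab0 <- score_sleep(ssw$eeg, ssw$emg, ssw$fs, emg_thresh = 0)
  expect_equal(mean(lab0$state == "wake"), 1)

  # raising the EMG threshold never increases wake time
  w <- vapply(c(5, 15, 40, 1e4), function(th)
    sum(score_sleep(ssw$eeg, ssw$emg, ssw$fs, emg_thresh = th)$state == "wake"),
    numeric(1))
  expect_true(all(diff(w) <= 0))
})

test_that("occupancy changes close to zero-sum and track ON-locked NREM", {
  ep <- data.frame(state = rep(c("wake", "NREM"), 10),
                   duration_s = rep(c(30, 40), 10))
  ss <- generate_state_session(ep, seed = 5)
  lab <- ss$labels
  tr <- make_trials(8, stim_s = 20, gap_s = 40, t0 = 40)
  occ <- state_occupancy_change(lab, tr, pre_s = 20)
  tot <- occ$wake$occ_on - occ$wake$occ_pre +
    occ$NREM$occ_on - occ$NREM$occ_pre +
    occ$REM$occ_on - occ$REM$occ_pre
  expect_lt(max(abs(tot)), 1e-9)
})

test_that("optical flow: static zero, translating square, luminance invariance", {
  mk <- function(off, gain = 1) {
    f <- matrix(0, 32, 32)
    f[10:15 + off, 10:15] <- gain
    f
  }
  same <- motion_from_frames(list(mk(0), mk(0), mk(0)), smooth_frames = 1)
  expect_equal(max(attr(same, "raw")), 0)

  frames <- lapply(0:10, mk)
  mt <- motion_from_frames(frames, smooth_frames = 3)
  raw <- attr(mt, "raw")
  expect_true(all(raw > 0))
  expect_lt(diff(range(raw)) / mean(raw), 0.1)  # approximately constant
  expect_equal(mean(mt$magnitude), 1, tolerance = 1e-9)

  bright <- lapply(0:10, mk, gain = 3)
  mtb <- motion_from_frames(bright, smooth_frames = 3)
  expect_equal(attr(mtb, "raw"), raw, tolerance = 1e-9)
  expect_error(motion_from_frames(list(mk(0))), "at least 2")
})

test_that("EEG-EMG correlation: identities, null rate, coupled recovery", {
  x <- rnorm(20)
  r <- eeg_emg_correlation(x, -x, seed = 1)
  expect_equal(r$r, -1)

  set.seed(43)
  nullrate <- mean(replicate(40, {
    eeg_emg_correlation(rnorm(30), rnorm(30), n_boot = 200,
                        seed = sample.int(1e6, 1))$significant
  }))
  expect_lte(nullrate, 0.15)

  d <- rnorm(100)
  e <- -0.4 * d + rnorm(100) * sqrt(1 - 0.16)
  rc <- eeg_emg_correlation(d, e, seed = 2)
  expect_lt(rc$r, 0)
  expect_true(rc$significant)
  expect_error(eeg_emg_correlation(rnorm(5), rnorm(5)), "at least 10")
})

test_that("shuffled-onset control is deterministic and covers a null statistic", {
  ep <- data.frame(state = c("wake", "NREM"), duration_s = c(30, 600))
  ss <- generate_state_session(ep, seed = 6)
  lab <- ss$labels
  set.seed(44)
  vals <- rnorm(700)
  stat <- function(onsets) mean(vals[onsets + 1])
  r1 <- shuffled_onset_control(stat, lab, n_onsets = 10, seed = 9)
  r2 <- shuffled_onset_control(stat, lab, n_onsets = 10, seed = 9)
  expect_identical(r1$null_ci, r2$null_ci)
  # a null statistic falls inside the shuffled CI
  true_stat <- stat(sample(lab$second[lab$state == "NREM" &
                                      lab$second > 60 &
                                      lab$second < 500], 10))
  expect_true(true_stat >= r1$null_ci[1] - 1 &&
              true_stat <= r1$null_ci[2] + 1)
  expect_error(shuffled_onset_control(stat, lab, n_onsets = 1e5, seed = 1),
               "not enough NREM")
})
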