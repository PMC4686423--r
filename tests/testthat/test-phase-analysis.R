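test_that("delta phase of a tone: slope, trough convention, sign flip", {
  fs <- 1000
  x <- cos(2 * pi * 2 * seq(0, 20 - 1 / fs, 1 / fs))
  ps <- delta_phase(x, fs)
  dp <- diff(ps$phase[ps$valid])
  dp[dp < -pi] <- dp[dp < -pi] + 2 * pi
  expect_equal(mean(dp) * fs, 4 * pi, tolerance = 0.01)

  # minima sit at +/- pi
  mins <- which(diff(sign(diff(x))) > 0) + 1
  mins <- mins[ps$valid[mins]]
  expect_true(all(abs(abs(ps$phase[mins])) > pi - 0.05))

  # sign flip shifts the phase by pi
  ps2 <- delta_phase(-x, fs)
  d <- localsleep:::wrap_pi(ps2$phase - ps$phase)
  expect_lt(max(abs(abs(d[ps$valid & ps2$valid]) - pi)), 0.05)
})

test_that("PLV identities, constant offsets, and independent-phase null", {
  set.seed(14)
  n <- 20000
  pa <- localsleep:::wrap_pi(cumsum(rnorm(n, 0.01, 0.002)))
  wins <- cbind(seq(1, 18001, by = 2000), seq(1000, 19000, by = 2000))
  r1 <- plv(pa, pa, wins, seed = 1)
  expect_equal(r1$plv, 1)
  expect_equal(r1$offset, 0)

  r2 <- plv(pa, localsleep:::wrap_pi(pa - 0.5), wins, seed = 1)
  expect_equal(r2$plv, 1, tolerance = 1e-9)
  expect_equal(r2$offset, 0.5, tolerance = 1e-9)
  expect_lt(r2$p, 0.05)
  expect_true(r2$offset_ci[1] <= 0.5 + 1e-9 && 0.5 <= r2$offset_ci[2] + 1e-9)

  hits <- replicate(20, {
    pb <- runif(n, -pi, pi)
    r <- plv(pa, pb, wins, n_perms = 200, n_boot = 50,
             seed = sample.int(1e6, 1))
    c(r$plv < 0.1, r$p > 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.75)
  expect_error(plv(pa, pa, wins[1:3, ]), "at least 6")
})

test_that("spike-phase MI: extremes, rotation invariance, von Mises oracle", {
  expect_equal(spike_phase_mi(rep(0.3, 50))$mi_bits, log2(10))
  u <- rep(seq(-pi + 0.1, pi - 0.1, length.out = 10), 12)
  expect_equal(spike_phase_mi(u)$mi_bits, 0, tolerance = 1e-12)

  set.seed(15)
  ph <- atan2(sin(stats::rnorm(5000)), cos(stats::rnorm(5000)))
  m1 <- spike_phase_mi(ph)
  rot <- localsleep:::wrap_pi(ph + 2 * pi / 10)  # one whole bin
  m2 <- spike_phase_mi(rot)
  expect_equal(m1$mi_bits, m2$mi_bits, tolerance = 1e-12)
  expect_true(m1$mi_bits <= log2(10) + 1e-12)

  # von Mises(kappa = 1) draws vs numeric integration of the binned density
  set.seed(16)
  n <- 10000
  vm <- replicate(n, {
    repeat {
      cand <- runif(1, -pi, pi)
      if (runif(1) < exp(1 * (cos(cand) - 1))) return(cand)
    }
  })
  got <- spike_phase_mi(vm)$mi_bits
  edges <- seq(-pi, pi, length.out = 11)
  p <- vapply(1:10, function(i)
    integrate(function(a) exp(cos(a)) / (2 * pi * besselI(1, 0)),
              edges[i], edges[i + 1])$value, numeric(1))
  p <- p / sum(p)
  oracle <- sum(p * log2(p)) + log2(10)
  expect_lt(abs(got - oracle), 0.02)
  expect_error(spike_phase_mi(numeric(0)), "no spikes")
  expect_error(spike_phase_mi(rep(1, 5)), "floor")
})

test_that("gamma-power MI matches the analytic binned profile", {
  fs <- 1000
  tt <- seq(0, 100 - 1 / fs, 1 / fs)
  # phase-independent amplitude: MI ~ 0
  x0 <- 150 * cos(2 * pi * 2 * tt) + cos(2 * pi * 85 * tt)
  expect_lt(gamma_power_mi(x0, fs)$mi_bits, 0.001)

  # amplitude 1 + 0.5 cos(phase): closed-form binned MI
  x <- 150 * cos(2 * pi * 2 * tt) +
    (1 + 0.5 * cos(2 * pi * 2 * tt)) * cos(2 * pi * 85 * tt)
  gm <- gamma_power_mi(x, fs)
  centers <- -pi + (1:100 - 0.5) * 2 * pi / 100
  p <- 1 + 0.5 * cos(centers)
  p <- p / sum(p)
  oracle <- sum(p * log2(p)) + log2(100)
  expect_lt(abs(gm$mi_bits - oracle) / oracle, 0.05)
  expect_lt(abs(gm$preferred_phase), 0.05)
})

test_that("MI change across trials tracks a laser-locked locking increase", {
  fs <- 1000
  tr <- make_trials(12)
  dur <- max(tr$offsets) + 40
  g <- generate_lfp(dur, tr, delta_effect_db = 3, seed = 21, fs = fs)
  on_mask <- rep(FALSE, round(dur * fs))
  ttt <- (seq_len(round(dur * fs)) - 1) / fs
  for (i in seq_along(tr$onsets))
    on_mask[ttt >= tr$onsets[i] & ttt < tr$offsets[i]] <- TRUE
  sp <- generate_spike_train(dur, 10, kappa = 1.5, phi0 = pi,
                             theta = g$ground_truth$theta, fs_phase = fs,
                             mod_mask = on_mask, seed = 22)
  ph <- delta_phase(g$trace, fs)
  mc <- mi_change(sp$spike_times, ph, tr)
  expect_gt(mc$effect$median, 0)
  expect_gt(mc$effect$ci[1], 0)
  expect_gt(mc$fraction_change, 0)

  # stationary unit: no MI change
  sp0 <- generate_spike_train(dur, 10, seed = 23)
  mc0 <- mi_change(sp0$spike_times, ph, tr)
  expect_true(mc0$effect$ci[1] <= 0 && mc0$effect$ci[2] >= 0)
})

test_that("circular kurtosis comparison separates tight from uniform groups", {
  set.seed(3)
  a <- rnorm(25, pi / 2, 0.15)
  b <- runif(25, -pi, pi)
  k <- circular_kurtosis_compare(a, b, 1000, seed = 1)
  expect_gt(k$diff, 0)
  expect_true(k$significant)

  same <- circular_kurtosis_compare(a, a + rnorm(25, 0, 0.1), 500, seed = 2)
  expect_lt(abs(same$diff), 0.2)
  expect_false(same$significant)
  expect_error(circular_kurtosis_compare(a[1:2], b), "at least 3")
})
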