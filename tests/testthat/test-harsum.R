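test_that("preprocessing z-scores, squares and flags constant windows", {
  set.seed(5)
  x <- channel_signal(rnorm(2000, mean = 10, sd = 3), 250, "x")
  z <- (x$samples - mean(x$samples)) / stats::sd(x$samples)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  pre <- preprocess_harsum(x, default_cfg)
  expect_true(pre$usable)
  expect_equal(pre$sd_sq, stats::sd(z^2))

  flat <- preprocess_harsum(channel_signal(rep(4, 2000), 250, "c"),
                            default_cfg)
  expect_false(flat$usable)
  est <- estimate_window_hr(channel_signal(rep(4, 2000), 250, "c"),
                            default_cfg)
  expect_equal(est$sqi, 0)
  expect_true(is.na(est$hr_bpm))
})

test_that("window spectrum localizes tones", {
  t <- (0:1999) / 250
  sp <- fft_spectrum(channel_signal(sin(2 * pi * 2 * t), 250, "s"),
                     default_cfg)
  expect_equal(sp$freqs_hz[which.max(sp$amps)], 2,
               tolerance = 2 * sp$df)
  two <- fft_spectrum(channel_signal(sin(2 * pi * 1.5 * t) +
                                       sin(2 * pi * 3 * t), 250, "s2"),
                      default_cfg)
  near <- function(f) max(two$amps[abs(two$freqs_hz - f) < 0.1])
  floor_amp <- stats::median(two$amps[two$freqs_hz > 4 & two$freqs_hz < 10])
  expect_gt(near(1.5), 50 * floor_amp)
  expect_gt(near(3), 50 * floor_amp)
})

test_that("kernel values match the closed form", {
  f0 <- 1.2
  expect_equal(kernel_value(f0, f0), 1)
  expect_equal(kernel_value(1.5 * f0, f0), -0.75)
  expect_equal(kernel_value(4 * f0, f0), 0)
  expect_equal(kernel_value(2 * f0, f0), 0.5)
  expect_equal(kernel_value(2.5 * f0, f0), -1 / 4 - 1 / 6)  # i=2, i=3 valleys
  # per-multiplier weights sum to zero (flat spectra score zero)
  for (i in c(1, 2, 3, 5, 7)) {
    expect_equal(1 / i - 2 * (1 / (2 * i)), 0)
  }
})

test_that("summation spectrum matches a direct double-loop oracle", {
  set.seed(11)
  freqs <- seq(0, 25, by = 0.01)
  cfg <- default_cfg
  for (rep_i in 1:5) {
    amps <- abs(rnorm(length(freqs)))
    spec <- make_spec(freqs, amps, band = c(0.5, 21))
    grid <- seq(0.8, 2.5, by = 0.1)
    hs <- harsum_spectrum(spec, grid, cfg)
    # oracle: exact integral of the piecewise-linear density, split at the
    # grid knots inside the aperture
    mass1 <- function(f) {
      lo <- f - cfg$harmonic_aperture_hz / 2
      hi <- f + cfg$harmonic_aperture_hz / 2
      xs <- c(lo, freqs[freqs > lo & freqs < hi], hi)
      vals <- stats::approx(freqs, amps, xs, rule = 2)$y
      sum(diff(xs) * (vals[-1] + vals[-length(vals)]) / 2)
    }
    oracle <- sapply(grid, function(f0) {
      s <- 0
      for (i in cfg$harmonic_set) {
        if ((i + 0.5) * f0 + cfg$harmonic_aperture_hz / 2 > 21) next
        s <- s + mass1(i * f0) / i -
          (mass1((i - 0.5) * f0) + mass1((i + 0.5) * f0)) / (2 * i)
      }
      s
    })
    expect_equal(hs, oracle, tolerance = 1e-9)
  }
})

test_that("impulse-train spectra score highest at the true fundamental", {
  freqs <- seq(0, 25, by = 0.005)
  f0 <- 1.4
  amps <- numeric(length(freqs))
  for (k in 1:7) amps[which.min(abs(freqs - k * f0))] <- 1
  spec <- make_spec(freqs, amps, band = c(0.5, 21))
  hs <- harsum_spectrum(spec, c(f0, 2 * f0), default_cfg)
  # all mass on the comb: HS(f0) = sum of per-bin mass / i over {1,2,3,5,7}
  mass <- 1 * 0.005
  expect_equal(hs[1], mass * sum(1 / c(1, 2, 3, 5, 7)), tolerance = 1e-9)
  expect_lt(hs[2], hs[1])  # odd harmonics of f0 fall on valleys of 2 f0
})

test_that("flat spectra score exactly zero", {
  freqs <- seq(0, 25, by = 0.01)
  spec <- make_spec(freqs, rep(0.7, length(freqs)), band = c(0.5, 21))
  hs <- harsum_spectrum(spec, seq(0.8, 2.8, by = 0.05), default_cfg)
  expect_lt(max(abs(hs)), 1e-9)
  expect_error(harsum_spectrum(spec, numeric(0), default_cfg), "empty")
})

test_that("window HR estimation is accurate and scale invariant", {
  y <- pulse_train(1.2, 250, 8) + 0.02 * sin(2 * pi * 50 * (0:1999) / 250)
  est <- estimate_window_hr(channel_signal(y, 250, "p"), default_cfg)
  expect_equal(est$hr_bpm, 72, tolerance = 2)
  expect_equal(est$hr_bpm, 60 * est$f0_hz)
  for (c_scale in c(12, -3)) {
    est2 <- estimate_window_hr(channel_signal(c_scale * y, 250, "p"),
                               default_cfg)
    expect_equal(est2$hr_bpm, est$hr_bpm)
    expect_equal(est2$sqi, est$sqi, tolerance = 1e-9)
  }
})

test_that("no octave error when a low-order harmonic dominates", {
  set.seed(21)
  t <- (0:1999) / 250
  for (f0 in c(1.1, 1.35)) {
    for (boost in c(2, 3)) {
      x <- cos(2 * pi * f0 * t) + boost * cos(2 * pi * 2 * f0 * t + 1) +
        0.7 * cos(2 * pi * 3 * f0 * t + 2) + rnorm(2000, 0, 0.2)
      est <- estimate_window_hr(channel_signal(x, 250, "h"), default_cfg)
      expect_equal(est$hr_bpm, 60 * f0, tolerance = 3)
    }
  }
  # severely attenuated fundamental on a pulse train
  y <- pulse_train(1.2, 250, 8)
  sp <- stats::fft(y)
  f_axis <- (seq_along(sp) - 1) * 250 / length(sp)
  kill <- (f_axis > 0.9 & f_axis < 1.5) | (f_axis > 250 - 1.5 & f_axis < 250 - 0.9)
  sp[kill] <- sp[kill] / 20
  y2 <- Re(stats::fft(sp, inverse = TRUE)) / length(sp)
  est2 <- estimate_window_hr(channel_signal(y2, 250, "a"), default_cfg)
  expect_equal(est2$hr_bpm, 72, tolerance = 3)
})

test_that("sliding windows follow the hop grid", {
  set.seed(2)
  x10 <- channel_signal(rnorm(2500), 250, "x")
  expect_equal(nrow(sliding_hr(x10, default_cfg)), 3)  # t = 0, 1, 2
  x8 <- channel_signal(rnorm(2000), 250, "x")
  expect_equal(nrow(sliding_hr(x8, default_cfg)), 1)
  expect_warning(out <- sliding_hr(channel_signal(rnorm(100), 250, "x"),
                                   default_cfg), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("constant-HR pulse trains give a stable sliding HR series", {
  y <- pulse_train(1.25, 250, 40) + stats::rnorm(10000, 0, 0.05)
  sl <- sliding_hr(channel_signal(y, 250, "p"), default_cfg)
  expect_equal(nrow(sl), 33)
  expect_lt(stats::sd(sl$hr_bpm), 1)
  expect_equal(stats::median(sl$hr_bpm), 75, tolerance = 1.5)
})
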