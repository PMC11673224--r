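test_that("recording round-trips through delimited text", {
  set.seed(1)
  rec <- recording(list(channel_signal(rnorm(800), 100, "PEC"),
                        channel_signal(rnorm(800), 100, "Radar0")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(length(back$channels), 2)
  expect_equal(back$sr_hz, 100)
  expect_equal(back$duration_s, 8)
  expect_equal(back$channels[[1]]$label, "PEC")
  expect_equal(back$channels[[2]]$samples, rec$channels[[2]]$samples,
               tolerance = 1e-12)
  # single-column file is a valid single-channel recording
  rec1 <- recording(list(channel_signal(sin(1:800), 100, "only")))
  write_recording(rec1, path)
  expect_equal(length(read_recording(path)$channels), 1)
})

test_that("malformed recordings are format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)            # no metadata line
  expect_error(read_recording(path), "sr_hz")
  writeLines(c("#sr_hz=100", "a,b", "1,2", "3"), path)  # ragged
  expect_error(read_recording(path), "format error")
  expect_error(recording(list(channel_signal(1:10, 100),
                              channel_signal(1:5, 100))), "equal length")
  expect_error(recording(list(channel_signal(1:10, 100),
                              channel_signal(1:10, 200))), "sampling rate")
})

test_that("IBI tables and beat annotations round-trip", {
  beats <- data.frame(
    time_s = c(1, 1.8, 2.61), ibi_ms = c(NA, 800, 810),
    source_channel = c("A", "A", "B"), sqi_beat = c(0.9, 0.95, 0.88),
    band_fl_hz = c(7, 7, 5)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_ibi_table(beats, path)
  back <- read_ibi_table(path)
  expect_equal(nrow(back), 3)
  expect_true(is.na(back$ibi_ms[1]))  # first beat has no predecessor
  expect_equal(back$ibi_ms[-1], beats$ibi_ms[-1], tolerance = 1e-6)
  expect_equal(back$time_s, beats$time_s, tolerance = 1e-6)
  expect_equal(back$source_channel, beats$source_channel)

  # empty series -> header-only file
  write_ibi_table(beats[0, ], path)
  expect_equal(nrow(read_ibi_table(path)), 0)

  ann <- beat_annotations(c(0.5, 1.33, 2.17), "simulator")
  write_beats(ann, path)
  back_ann <- read_beats(path)
  expect_equal(back_ann$beat_times_s, ann$beat_times_s, tolerance = 1e-6)
  expect_equal(back_ann$source, "simulator")
  expect_error(beat_annotations(c(1, 1)), "increasing")
})

test_that("quadratic spline resampling reproduces low-degree polynomials", {
  const <- channel_signal(rep(2.5, 100), 100, "c")
  up <- resample_quadratic_spline(const, 400)
  expect_equal(length(up$samples), 400)
  expect_equal(up$samples, rep(2.5, 400), tolerance = 1e-10)

  n <- 250
  ramp <- channel_signal(seq(0, 2, length.out = n), 250, "r")
  up2 <- resample_quadratic_spline(ramp, 1000)
  t_out <- (seq_along(up2$samples) - 1) / 1000
  slope <- 2 / ((n - 1) / 250)
  expect_lt(max(abs(up2$samples - slope * t_out)), 1e-9 * 2)

  quad <- channel_signal((0:99)^2 / 99^2, 100, "q")
  up3 <- resample_quadratic_spline(quad, 500)
  t3 <- (seq_along(up3$samples) - 1) / 500
  expect_lt(max(abs(up3$samples - (t3 * 100)^2 / 99^2)), 1e-8)

  expect_error(resample_quadratic_spline(channel_signal(c(1, 2), 10, "x"),
                                         100), "3 samples")
})

test_that("sine upsampling stays within 1% RMS of the analytic waveform", {
  t <- (0:199) / 100
  s <- channel_signal(sin(2 * pi * 2 * t), 100, "s")
  up <- resample_quadratic_spline(s, 1000)
  truth <- sin(2 * pi * 2 * (seq_along(up$samples) - 1) / 1000)
  expect_lt(sqrt(mean((up$samples - truth)^2)), 0.01)
})

test_that("decimation then spline restoration round-trips band-limited signals", {
  sr <- 1000
  t <- (0:(2 * sr - 1)) / sr
  y <- sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 13 * t)
  ch <- channel_signal(y, sr, "b")
  down <- decimate_channel(ch, 10)
  expect_equal(down$sr_hz, 100)
  back <- resample_quadratic_spline(down, sr)
  m <- min(length(back$samples), length(y))
  expect_lt(sqrt(mean((back$samples[1:m] - y[1:m])^2)) / stats::sd(y), 0.01)
})
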