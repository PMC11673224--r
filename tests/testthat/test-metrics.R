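test_that("windowed HR metrics reproduce worked values", {
  cfg <- default_cfg
  # reference beats every 60/72 s -> 72 bpm in every window
  ref <- beat_annotations(seq(0.2, 20, by = 60 / 72))
  est <- data.frame(window_start_s = 0:11,
                    hr_bpm = c(rep(71, 10), NA, NA),
                    analyzed = c(rep(TRUE, 10), FALSE, FALSE))
  rep <- hr_metrics(est, ref, cfg)
  expect_equal(rep$mae_bpm, 1, tolerance = 1e-9)
  expect_equal(rep$cov_pct, 100 * 10 / 12, tolerance = 1e-9)
  expect_equal(rep$sdae_bpm, 0, tolerance = 1e-9)  # constant absolute error
  expect_equal(rep$mrae_pct, 100 / 72, tolerance = 1e-9)
  # perfect estimates give zero errors
  est2 <- est; est2$hr_bpm <- 72; est2$analyzed <- TRUE
  rep2 <- hr_metrics(est2, ref, cfg)
  expect_equal(rep2$mae_bpm, 0, tolerance = 1e-9)
  expect_equal(rep2$cov_pct, 100)
})

test_that("IBI metrics reproduce the worked interval pairs", {
  # reference RR = 800, 810 ms; estimates JJ = 805, 805 ms
  ref <- beat_annotations(c(1, 1.8, 2.61))
  est <- c(1.0, 1.805, 2.61)
  rep <- ibi_metrics(est, ref)
  expect_equal(rep$mae_ms, 5, tolerance = 1e-9)
  expect_equal(rep$sdae_ms, 0, tolerance = 1e-9)
  expect_equal(rep$prec_pct, 100)
  expect_equal(rep$det_pct, 100 * 2 / 3)
  expect_equal(rep$n_all_ref_beats, 3)

  # identical series: zero error, Det = paired / all
  ref2 <- beat_annotations(seq(1, 30, by = 0.8))
  rep2 <- ibi_metrics(ref2$beat_times_s, ref2)
  expect_equal(rep2$mae_ms, 0, tolerance = 1e-9)
  expect_equal(rep2$prec_pct, 100)
  expect_equal(rep2$det_pct,
               100 * (length(ref2$beat_times_s) - 1) /
                 length(ref2$beat_times_s))

  # one interval off by 50 ms among 10: inclusive 30 ms rule
  t <- seq(1, 9.9, by = 0.8)   # 12 beats, 11 intervals
  est3 <- t; est3[6] <- t[6] + 0.05
  rep3 <- ibi_metrics(est3, beat_annotations(t))
  expect_equal(rep3$n_incorrect, 2)  # both intervals touching beat 6
  expect_equal(rep3$prec_pct, 100 * 9 / 11, tolerance = 1e-9)
  # exactly 30 ms is correct (inclusive)
  est4 <- t; est4[6] <- t[6] + 0.03
  expect_equal(ibi_metrics(est4, beat_annotations(t))$n_incorrect, 0)
  expect_error(ibi_metrics(est3, beat_annotations(1)), "2 reference")
})

test_that("IBI metrics agree with a naive oracle on random inputs", {
  set.seed(59)
  for (rep_i in 1:20) {
    n <- sample(10:30, 1)
    ref_t <- cumsum(c(1, runif(n - 1, 0.7, 0.9)))
    keep <- sort(sample(n, n - sample(0:3, 1)))
    est_t <- ref_t[keep] + runif(length(keep), -0.02, 0.02)
    rep <- ibi_metrics(est_t, beat_annotations(ref_t))
    # oracle: direct pairing by construction (offsets < half an interval)
    rr <- jj <- numeric(0)
    for (k in 2:length(keep)) {
      if (keep[k] != keep[k - 1] + 1) next
      rr <- c(rr, (ref_t[keep[k]] - ref_t[keep[k - 1]]) * 1000)
      jj <- c(jj, (est_t[k] - est_t[k - 1]) * 1000)
    }
    ae <- abs(rr - jj)
    expect_equal(rep$mae_ms, mean(ae), tolerance = 1e-9)
    expect_equal(rep$mrae_pct, mean(ae / rr) * 100, tolerance = 1e-9)
    expect_equal(rep$sdae_ms, sqrt(mean((ae - mean(ae))^2)), tolerance = 1e-9)
    expect_equal(rep$n_correct, sum(ae <= 30))
    expect_equal(rep$det_pct, 100 * sum(ae <= 30) / n, tolerance = 1e-9)
    # detection rate never exceeds precision when beats are unpaired
    if (rep$n_all_ref_beats > rep$n_correct + rep$n_incorrect) {
      expect_lte(rep$det_pct, rep$prec_pct)
    }
    # scale consistency of the relative error
    rep2x <- ibi_metrics(2 * est_t, beat_annotations(2 * ref_t))
    expect_equal(rep2x$mrae_pct, rep$mrae_pct, tolerance = 1e-9)
  }
})

test_that("agreement limits follow the closed form", {
  ba <- bland_altman(c(800, 810, 820), c(800, 810, 820))
  expect_equal(ba$bias_ms, 0)
  expect_equal(ba$loa_low_ms, 0)
  d <- c(5, -5)
  ba2 <- bland_altman(c(800, 800), c(805, 795))
  expect_equal(ba2$bias_ms, 0)
  expect_equal(ba2$loa_high_ms, 1.96 * stats::sd(d))
  ba3 <- bland_altman(c(800, 810, 790), c(805, 815, 795))
  expect_equal(ba3$bias_ms, 5)
  expect_equal(ba3$loa_low_ms, 5)  # constant offset: zero-width limits
  expect_equal(ba3$loa_high_ms, 5)
})
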