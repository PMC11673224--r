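test_that("template length is one rounded beat period", {
  expect_equal(template_length(60, 1000), 1000L)
  expect_equal(template_length(75, 250), 200L)
  expect_equal(template_length(72, 250), 208L)  # round(208.33)
})

test_that("segments are centered on interior strict maxima", {
  s <- rep(0, 100)
  s[c(20, 50, 80)] <- c(1, 2, 1.5)
  ex <- extract_segments(s, 20)
  expect_equal(ex$p_index, c(20, 50, 80))
  expect_equal(nrow(ex$segments), 20)
  expect_equal(ex$segments[11, ], c(1, 2, 1.5))  # center sample (floor(L/2)+1)

  expect_error(extract_segments(seq_len(100), 10), "maxima")  # monotone ramp
  # plateau counts once, at its first sample
  p <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, 0, 0)
  ex2 <- extract_segments(p, 4)
  expect_equal(ex2$p_index, 4)
})

test_that("correlation matrix matches a two-pass Pearson oracle", {
  set.seed(19)
  seg <- matrix(rnorm(5 * 40), nrow = 40)
  cm <- correlation_matrix(seg)
  expect_equal(dim(cm), c(5, 5))
  expect_equal(diag(cm), rep(1, 5))
  expect_equal(cm, t(cm))
  oracle <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    a <- seg[, i]; b <- seg[, j]
    oracle[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cm, oracle, tolerance = 1e-12)

  seg2 <- cbind(seg[, 1], seg[, 1], -seg[, 1], rep(2, 40))
  cm2 <- correlation_matrix(seg2)
  expect_equal(cm2[1, 2], 1)
  expect_equal(cm2[1, 3], -1)
  expect_equal(cm2[1, 4], 0)  # zero-variance column defined as 0
})

test_that("sequential clustering follows the admission rule", {
  # all mutually identical -> one cluster
  cm1 <- matrix(1, 4, 4)
  expect_equal(bsas_cluster(cm1, 0.75), rep(1L, 4))
  # alternating orthogonal shapes -> two alternating clusters
  cm2 <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) cm2[i, j] <- ifelse((i - j) %% 2 == 0, 0.95, 0.05)
  diag(cm2) <- 1
  expect_equal(bsas_cluster(cm2, 0.75), rep(c(1L, 2L), 3))
  # nothing correlates -> all singletons
  cm3 <- matrix(0.1, 5, 5); diag(cm3) <- 1
  expect_equal(bsas_cluster(cm3, 0.75), 1:5)
})

test_that("clustering postconditions hold on random instances", {
  set.seed(23)
  for (rep_i in 1:20) {
    n <- sample(4:12, 1)
    seg <- matrix(rnorm(30 * n), nrow = 30)
    cm <- correlation_matrix(seg)
    assign <- bsas_cluster(cm, 0.75)
    # partition: every segment assigned exactly one cluster id
    expect_true(all(assign >= 1))
    expect_equal(sort(unique(assign)), seq_len(max(assign)))
    # admission postcondition, re-checked from insertion order
    for (i in seq_len(n)[-1]) {
      prior <- which(assign[seq_len(i - 1)] == assign[i])
      if (length(prior)) expect_gte(min(cm[i, prior]), 0.75)
    }
    # oracle agreement
    expect_equal(assign, bsas_oracle(cm, 0.75))
  }
})

test_that("primary selection follows the cluster ranking and correlation sum", {
  # mean L2 norms {2, 5}: second cluster wins under the norm rule
  seg <- cbind(c(2, 0, 0), c(0, 5, 0), c(0, 0, 5))
  assign <- c(1L, 2L, 2L)
  cm <- correlation_matrix(seg)
  expect_equal(select_primary(seg, assign, cm, "l2norm")$cluster, 2L)
  # correlation-sum template choice inside a 3-member cluster
  cm2 <- matrix(c(1, 0.95, 0.85,
                  0.95, 1, 0.95,
                  0.85, 0.95, 1), 3, 3)
  seg2 <- matrix(rnorm(30), 10, 3)
  sel <- select_primary(seg2, c(1L, 1L, 1L), cm2, "l2norm")
  expect_equal(sel$template, 2L)  # highest row sum
  # singleton winning cluster yields its only member
  sel1 <- select_primary(cbind(c(0, 9, 0)), 1L, matrix(1, 1, 1), "center")
  expect_equal(sel1$template, 1L)
})

test_that("the gap rule produces a second template only when one is due", {
  L <- 10
  seg <- matrix(rnorm(5 * 21), 21, 5)
  cm <- correlation_matrix(seg)
  # primary cluster covering every beat: gaps ~ L, no second template
  expect_null(second_template(seg, c(10, 20, 30, 40, 50),
                              c(1L, 1L, 1L, 1L, 1L), cm, 1L, L))
  # alternating clusters: primary gaps of 2L > 1.5L, competitor in the gap
  p <- c(10, 20, 30, 40, 50)
  assign <- c(1L, 2L, 1L, 2L, 1L)
  sec <- second_template(seg, p, assign, cm, 1L, L)
  expect_false(is.null(sec))
  expect_equal(sec$cluster, 2L)
  # a wide gap with no competing cluster inside it yields nothing
  expect_null(second_template(seg[, 1:3], c(10, 40, 70), c(1L, 1L, 1L),
                              correlation_matrix(seg[, 1:3]), 1L, L))
})

test_that("selection and gap logic agree with brute-force oracles", {
  set.seed(29)
  for (rep_i in 1:30) {
    n <- sample(5:12, 1)
    L <- 12
    seg <- matrix(rnorm(25 * n), 25, n)
    p_index <- sort(sample(20:300, n))
    cm <- correlation_matrix(seg)
    assign <- bsas_cluster(cm, 0.6)
    for (rule in c("center", "l2norm")) {
      got <- select_primary(seg, assign, cm, rule)
      want <- primary_oracle(seg, assign, cm, rule)
      expect_equal(got, want)
      got2 <- second_template(seg, p_index, assign, cm, got$cluster, L, rule)
      want2 <- second_oracle(seg, p_index, assign, cm, want$cluster, L, rule)
      expect_equal(got2, want2)
    }
  }
})

test_that("template groups recover injected morphologies", {
  cfg <- default_cfg
  # single morphology: one template matching the injected waveshape
  scn <- cvs_scenario(n_channels = 1, archetypes = "piezo", seed = 31,
                      duration_s = 12, snr_db = 25)
  g <- generate_recording(scn)
  band <- bandpass_bidirectional(g$recording$channels[[1]], 7, 40, 3)
  hr <- estimate_window_hr(channel_signal(band$samples[1:2000], 250, "w"),
                           cfg)$hr_bpm
  grp <- build_template_group(band$samples[1:2000], hr, 250, cfg)
  expect_equal(ncol(grp$templates), 1)
  shape <- render_waveshape("piezo", 1, 250)
  ref <- bandpass_bidirectional(
    channel_signal(c(numeric(500), shape$values, numeric(500)), 250, "s"),
    7, 40, 3)$samples
  pk <- which.max(ref)
  ref_win <- ref[(pk - floor(grp$L / 2)):(pk + ceiling(grp$L / 2) - 1)]
  expect_gt(maxlag_cor(grp$templates[, 1], ref_win, 60), 0.95)
  # templates live inside the primary cluster
  expect_true(all(grp$assign[grp$assign == grp$assign[1]] >= 1))
})
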