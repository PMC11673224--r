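# End-to-end orchestration: filter bank -> windowed harmonic-summation HR and
# quality -> band/channel selection -> template groups -> per-channel beat
# tracking with update triggers -> beat-level fusion.

#' Adjust a configuration for an evaluation mode
#'
#' `"hs"`, `"mc"` and `"sc"` leave the configuration unchanged (they differ
#' only in which channels are fed in); `"hs-nobs"` disables optimal band
#' selection by restricting the candidate set to the single 3 Hz low cutoff.
#'
#' @param cfg an [hsf_config()].
#' @param mode one of `"hs"`, `"mc"`, `"sc"`, `"hs-nobs"`.
#' @return an [hsf_config()].
#' @export
config_for_mode <- function(cfg, mode = c("hs", "mc", "sc", "hs-nobs")) {
  mode <- match.arg(mode)
  if (mode == "hs-nobs") {
    cfg$candidate_fl_hz <- 3
    validate_hsf_config(cfg)
  }
  cfg
}

# track one channel across epochs: (re)select its band, build a template
# group, run detection until an update trigger, repeat
track_channel <- function(cands, hr_mat, sqi_mat, decisions, all_fail_starts,
                          sr_hz, cfg, label) {
  nwin <- nrow(sqi_mat)
  wlen <- round(cfg$window_s * sr_hz)
  step <- round(cfg$step_s * sr_hz)
  beats <- list()
  gaps <- list()
  events <- list()
  wa <- 1L
  last_beat <- NA_integer_
  while (wa <= nwin) {
    # next admissible window for this channel
    w <- wa
    while (w <= nwin && decisions[[w]]$status != "selected") w <- w + 1L
    if (w > nwin) break
    dec <- decisions[[w]]
    bidx <- which(vapply(cands, function(cc) cc$fl_hz, numeric(1)) ==
                    dec$fl_hz)[1]
    y <- cands[[bidx]]$filtered$samples
    hr <- hr_mat[w, bidx]
    if (!is.finite(hr)) { wa <- w + 1L; next }
    ws <- (w - 1L) * step + 1L
    grp <- tryCatch(
      build_template_group(y[ws:(ws + wlen - 1L)], hr, sr_hz, cfg),
      error = function(e) NULL
    )
    if (is.null(grp)) { wa <- w + 1L; next }
    hi_off <- round((1 + cfg$v_hrv) * grp$L)
    anchor <- if (!is.na(last_beat) && last_beat >= ws - hi_off) {
      last_beat
    } else NA_integer_
    from <- if (is.na(anchor)) {
      max(ws, if (is.na(last_beat)) 1L else
        last_beat + round((1 - cfg$v_hrv) * grp$L))
    } else ws
    stops <- all_fail_starts[all_fail_starts > ws]
    det <- detect_beats(y, grp, cands[[bidx]]$beta, sr_hz, cfg,
                        from_sample = from, anchor_sample = anchor,
                        stop_samples = stops)
    if (nrow(det$beats)) {
      det$beats$fl_hz <- dec$fl_hz
      det$beats$beta <- cands[[bidx]]$beta
      beats[[length(beats) + 1]] <- det$beats
      last_beat <- det$beats$p_index[nrow(det$beats)]
    }
    if (nrow(det$gaps)) gaps[[length(gaps) + 1]] <- det$gaps
    if (det$trigger == "none") break
    events[[length(events) + 1]] <-
      data.frame(time_s = det$t_stop, trigger = det$trigger,
                 window = w, fl_hz = dec$fl_hz)
    # rebuild on the most recent full window at the stop point
    w_recent <- floor((det$t_stop - cfg$window_s) / cfg$step_s) + 1
    wa <- max(w + 1L, min(nwin, as.integer(w_recent)))
  }
  list(
    beats = if (length(beats)) do.call(rbind, beats) else {
      cbind(empty_beats(), fl_hz = numeric(0), beta = numeric(0))
    },
    gaps = if (length(gaps)) do.call(rbind, gaps) else empty_gaps(),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(time_s = numeric(0), trigger = character(0),
                 window = integer(0), fl_hz = numeric(0))
  )
}

#' Run the full IBI-extraction pipeline on a recording
#'
#' Per channel: build the band-candidate filter bank, estimate heart rate and
#' window quality per band on sliding windows, select the operating band (or
#' discard the channel) per window, extract a template group on the first
#' admissible window, and track beats by peak-restricted template matching
#' with automatic template updates. Finally fuse all channels' beats into one
#' IBI series by per-beat quality.
#'
#' @param rec a [recording()] at least one analysis window long.
#' @param cfg an [hsf_config()].
#' @return object of class `hsf_result`: `fused` (a `fused_ibi`),
#'   `sequences` (named list of per-channel beat data frames), `window_hr`
#'   (per-window fused HR estimate with `analyzed` flag), `decisions`
#'   (per-window per-channel band decision log), `gaps`, `events`,
#'   `coverage_pct`, `config`.
#' @export
run_hsf_ibi <- function(rec, cfg = hsf_config()) {
  stopifnot(inherits(rec, "recording"))
  sr <- rec$sr_hz
  nch <- length(rec$channels)
  labels <- vapply(rec$channels, function(ch) ch$label, character(1))
  wlen <- round(cfg$window_s * sr)
  step <- round(cfg$step_s * sr)
  n <- length(rec$channels[[1]]$samples)
  if (n < wlen) stop("recording shorter than one analysis window")
  nwin <- (n - wlen) %/% step + 1L

  cands <- vector("list", nch)
  hr_arr <- vector("list", nch)
  sqi_arr <- vector("list", nch)
  for (c_i in seq_len(nch)) {
    cands[[c_i]] <- build_band_candidates(rec$channels[[c_i]], cfg)
    nb <- length(cands[[c_i]])
    hr_m <- matrix(NA_real_, nwin, nb)
    sqi_m <- matrix(0, nwin, nb)
    for (b_i in seq_len(nb)) {
      sl <- sliding_hr(cands[[c_i]][[b_i]]$filtered, cfg)
      hr_m[, b_i] <- sl$hr_bpm
      sqi_m[, b_i] <- sl$sqi
    }
    hr_arr[[c_i]] <- hr_m
    sqi_arr[[c_i]] <- sqi_m
  }

  win_starts <- (seq_len(nwin) - 1) * cfg$step_s
  decisions <- vector("list", nch)   # per channel: list over windows
  dec_log <- list()
  for (c_i in seq_len(nch)) {
    fls <- vapply(cands[[c_i]], function(cc) cc$fl_hz, numeric(1))
    decisions[[c_i]] <- lapply(seq_len(nwin), function(w) {
      select_band(stats::setNames(sqi_arr[[c_i]][w, ], fls), cfg)
    })
    dec_log[[c_i]] <- data.frame(
      window_start_s = win_starts,
      channel = labels[c_i],
      rule = vapply(decisions[[c_i]], function(d) d$rule, integer(1)),
      fl_hz = vapply(decisions[[c_i]], function(d) d$fl_hz, numeric(1)),
      sqi = vapply(decisions[[c_i]], function(d) d$sqi, numeric(1))
    )
  }
  admitted <- vapply(seq_len(nwin), function(w) {
    any(vapply(decisions, function(dch) dch[[w]]$status == "selected",
               logical(1)))
  }, logical(1))
  all_fail_starts <- ((which(!admitted)) - 1L) * step + 1L

  sequences <- list()
  gaps <- list()
  events <- list()
  for (c_i in seq_len(nch)) {
    tr <- track_channel(cands[[c_i]], hr_arr[[c_i]], sqi_arr[[c_i]],
                        decisions[[c_i]], all_fail_starts, sr, cfg,
                        labels[c_i])
    sequences[[labels[c_i]]] <- tr$beats
    if (nrow(tr$gaps)) {
      tr$gaps$channel <- labels[c_i]
      gaps[[length(gaps) + 1]] <- tr$gaps
    }
    if (nrow(tr$events)) {
      tr$events$channel <- labels[c_i]
      events[[length(events) + 1]] <- tr$events
    }
  }
  fused <- fuse_sequences(sequences, cfg)

  # fused window HR: the admitted channel/band with the highest quality
  win_hr <- vapply(seq_len(nwin), function(w) {
    best <- NA_real_; best_sqi <- -Inf
    for (c_i in seq_len(nch)) {
      d <- decisions[[c_i]][[w]]
      if (d$status != "selected") next
      b_i <- which(vapply(cands[[c_i]], function(cc) cc$fl_hz,
                          numeric(1)) == d$fl_hz)[1]
      if (d$sqi > best_sqi) { best_sqi <- d$sqi; best <- hr_arr[[c_i]][w, b_i] }
    }
    best
  }, numeric(1))

  structure(list(
    fused = fused,
    sequences = sequences,
    window_hr = data.frame(window_start_s = win_starts, hr_bpm = win_hr,
                           analyzed = admitted),
    decisions = do.call(rbind, dec_log),
    gaps = if (length(gaps)) do.call(rbind, gaps) else empty_gaps(),
    events = if (length(events)) do.call(rbind, events) else NULL,
    coverage_pct = 100 * mean(admitted),
    config = cfg
  ), class = "hsf_result")
}

#' @export
print.hsf_result <- function(x, ...) {
  cat(sprintf("<hsf_result: %d fused beats from %d channel(s), coverage %.1f%%>\n",
              nrow(x$fused$beats), length(x$sequences), x$coverage_pct))
  invisible(x)
}
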