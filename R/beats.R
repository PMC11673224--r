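# Peak-restricted template matching: Pearson correlation of each template
# with the signal window centered at every local maximum, then a sequential
# search that steps from beat to beat inside the physiological HRV window.

#' Template correlations at signal peaks
#'
#' For every strict local maximum with a full centered window of length `L`,
#' the Pearson correlation of that window with each template. Correlation is
#' evaluated only at peaks, never per sample, so the work per window is
#' (number of peaks) x (number of templates).
#'
#' @param y numeric vector: the band-filtered channel.
#' @param templates L x k template matrix.
#' @param from,to optional sample range restricting the peaks considered.
#' @return list: `p_index` (peak positions) and `ccf` (n_peaks x k matrix).
#' @export
ccf_at_peaks <- function(y, templates, from = 1L, to = length(y)) {
  L <- nrow(templates)
  half_lo <- floor(L / 2)
  half_hi <- ceiling(L / 2)
  pk <- local_maxima(y)
  pk <- pk[pk >= from & pk <= to &
             pk - half_lo >= 1 & pk + half_hi - 1 <= length(y)]
  if (!length(pk)) {
    return(list(p_index = integer(0),
                ccf = matrix(numeric(0), ncol = ncol(templates))))
  }
  win <- vapply(pk, function(p) y[(p - half_lo):(p + half_hi - 1)],
                numeric(L))
  win <- matrix(win, nrow = L)
  cc <- suppressWarnings(stats::cor(win, templates))
  cc[!is.finite(cc)] <- 0
  list(p_index = pk, ccf = matrix(cc, ncol = ncol(templates)))
}

#' Per-channel heartbeat detection by template matching
#'
#' Bootstraps on the best-matching peak within the first 2 s of the search
#' region, then walks forward: after each confirmed beat, candidate peaks are
#' those inside `[(1 - v) L, (1 + v) L]` after it, scored by the highest
#' correlation among the eligible templates (templates whose correlation at
#' the previous beat exceeded `theta_beat`; when none qualifies all templates
#' compete). The per-beat quality index is `beta` times the best correlation
#' over all templates. An empty search window is a missed beat: the anchor
#' advances by one expected period and no interval is emitted across the gap.
#'
#' Detection stops and reports a trigger when quality stays below
#' `theta_beat` for `consecutive_low_sqi_for_update` beats, after
#' `max_consecutive_misses` consecutive misses, or on reaching a forced-stop
#' sample (used when the window-level quality of every channel has failed).
#'
#' @param y numeric vector: band-filtered channel samples.
#' @param group a [build_template_group()] result.
#' @param beta band weight of this channel's selected band.
#' @param sr_hz sampling rate (Hz).
#' @param cfg an [hsf_config()].
#' @param from_sample first sample of the search region.
#' @param anchor_sample optional last confirmed beat (sample) to resume from;
#'   `NA` bootstraps inside `[from_sample, from_sample + 2 s]`.
#' @param stop_samples sorted sample positions forcing a template update.
#' @return list: `beats` (data frame `p_index`, `time_s`, `ibi_ms`,
#'   `sqi_beat`, `template_used`, `prev_sqi`), `gaps` (data frame `start_s`,
#'   `end_s`), `trigger` (`"none"`, `"low_sqi"`, `"miss"`, `"harsum_fail"`,
#'   `"no_bootstrap"`), `t_stop` (s).
#' @export
detect_beats <- function(y, group, beta, sr_hz, cfg,
                         from_sample = 1L, anchor_sample = NA_integer_,
                         stop_samples = integer(0)) {
  L <- group$L
  trim <- round(cfg$edge_trim_s * sr_hz)
  n <- length(y)
  pks <- ccf_at_peaks(y, group$templates,
                      from = max(1L, trim + 1L, from_sample - L),
                      to = n - trim)
  ntpl <- ncol(group$templates)
  lo_off <- round((1 - cfg$v_hrv) * L)
  hi_off <- round((1 + cfg$v_hrv) * L)

  beats_p <- integer(0); beats_sqi <- numeric(0); beats_tpl <- integer(0)
  beats_ibi <- numeric(0); beats_prev <- numeric(0)
  gaps <- list()
  trigger <- "none"; t_stop <- NA_real_
  low_ct <- 0L; miss_ct <- 0L
  gap_open <- NA_real_

  best_all <- if (length(pks$p_index)) {
    apply(pks$ccf, 1, max)
  } else numeric(0)

  # bootstrap
  if (is.na(anchor_sample)) {
    bs_lo <- from_sample
    bs_hi <- from_sample + round(2 * sr_hz)
    cand <- which(pks$p_index >= bs_lo & pks$p_index <= bs_hi)
    if (!length(cand)) {
      return(list(beats = empty_beats(), gaps = empty_gaps(),
                  trigger = "no_bootstrap",
                  t_stop = from_sample / sr_hz))
    }
    k <- cand[which.max(best_all[cand])]
    prev <- pks$p_index[k]
    prev_ccf <- pks$ccf[k, ]
    sqi <- beta * max(prev_ccf)
    beats_p <- prev; beats_sqi <- sqi
    beats_tpl <- which.max(prev_ccf); beats_ibi <- NA_real_
    beats_prev <- NA_real_
    low_ct <- if (sqi < cfg$theta_beat) 1L else 0L
    anchored <- TRUE
  } else {
    prev <- anchor_sample
    prev_ccf <- rep(1, ntpl)  # resume: all templates eligible
    anchored <- FALSE          # anchor beat already emitted by the caller
  }
  last_emitted <- prev

  repeat {
    lo <- prev + lo_off
    hi <- prev + hi_off
    if (length(stop_samples)) {
      s_hit <- stop_samples[stop_samples > prev & stop_samples <= hi]
      if (length(s_hit)) {
        trigger <- "harsum_fail"
        t_stop <- s_hit[1] / sr_hz
        break
      }
    }
    if (lo > n - trim) break
    cand <- which(pks$p_index >= lo & pks$p_index <= hi)
    if (!length(cand)) {
      if (is.na(gap_open)) gap_open <- last_emitted / sr_hz
      prev <- prev + L
      miss_ct <- miss_ct + 1L
      if (miss_ct >= cfg$max_consecutive_misses) {
        trigger <- "miss"
        t_stop <- prev / sr_hz
        break
      }
      next
    }
    eligible <- which(prev_ccf > cfg$theta_beat)
    if (!length(eligible)) eligible <- seq_len(ntpl)
    score <- apply(pks$ccf[cand, eligible, drop = FALSE], 1, max)
    k <- cand[which.max(score)]
    p <- pks$p_index[k]
    row <- pks$ccf[k, ]
    tpl <- eligible[which.max(row[eligible])]
    sqi <- beta * max(row)
    if (!is.na(gap_open)) {
      gaps[[length(gaps) + 1]] <- c(gap_open, p / sr_hz)
      gap_open <- NA_real_
      ibi <- NA_real_  # no interval across a gap
    } else {
      ibi <- (p - last_emitted) / sr_hz * 1000
    }
    prev_sqi <- if (length(beats_sqi)) beats_sqi[length(beats_sqi)]
                else NA_real_
    beats_p <- c(beats_p, p)
    beats_sqi <- c(beats_sqi, sqi)
    beats_tpl <- c(beats_tpl, tpl)
    beats_ibi <- c(beats_ibi, ibi)
    beats_prev <- c(beats_prev, prev_sqi)
    last_emitted <- p
    prev <- p
    prev_ccf <- row
    miss_ct <- 0L
    low_ct <- if (sqi < cfg$theta_beat) low_ct + 1L else 0L
    if (low_ct >= cfg$consecutive_low_sqi_for_update) {
      trigger <- "low_sqi"
      t_stop <- p / sr_hz
      break
    }
  }

  beats <- data.frame(
    p_index = beats_p,
    time_s = (beats_p - 1) / sr_hz,
    ibi_ms = beats_ibi,
    sqi_beat = beats_sqi,
    template_used = beats_tpl,
    prev_sqi = beats_prev
  )
  gdf <- if (length(gaps)) {
    g <- do.call(rbind, gaps)
    data.frame(start_s = g[, 1], end_s = g[, 2])
  } else empty_gaps()
  list(beats = beats, gaps = gdf, trigger = trigger, t_stop = t_stop)
}

empty_beats <- function() {
  data.frame(p_index = integer(0), time_s = numeric(0), ibi_ms = numeric(0),
             sqi_beat = numeric(0), template_used = integer(0),
             prev_sqi = numeric(0))
}

empty_gaps <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0))
}
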