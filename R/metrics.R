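# Evaluation metrics: windowed mean-HR errors with coverage, beat-level IBI
# errors with the 30 ms correctness rule, and Bland-Altman agreement.

#' Windowed mean heart-rate metrics
#'
#' Reference HR of a window is `60 / mean(reference IBIs inside the window)`;
#' windows without at least two reference beats are excluded from the error
#' statistics but still count in the coverage denominator. Coverage is the
#' percentage of windows the pipeline analyzed (at least one admitted
#' channel).
#'
#' @param hr_est data frame with `window_start_s`, `hr_bpm` and logical
#'   `analyzed` (e.g. the `window_hr` table of [run_hsf_ibi()]).
#' @param ref_beats a [beat_annotations()].
#' @param cfg an [hsf_config()].
#' @return list of class `hr_report`: `mae_bpm`, `mrae_pct`, `sdae_bpm`,
#'   `cov_pct`, `n_windows`, `n_scored`.
#' @export
hr_metrics <- function(hr_est, ref_beats, cfg) {
  stopifnot(nrow(hr_est) >= 1)
  ref_t <- ref_beats$beat_times_s
  ref_hr <- vapply(hr_est$window_start_s, function(t0) {
    inw <- ref_t[ref_t >= t0 & ref_t < t0 + cfg$window_s]
    if (length(inw) < 2) return(NA_real_)
    60 / mean(diff(inw))
  }, numeric(1))
  scored <- hr_est$analyzed & !is.na(hr_est$hr_bpm) & !is.na(ref_hr)
  ae <- abs(hr_est$hr_bpm[scored] - ref_hr[scored])
  structure(list(
    mae_bpm = mean(ae),
    mrae_pct = mean(ae / ref_hr[scored]) * 100,
    sdae_bpm = sqrt(mean((ae - mean(ae))^2)),
    cov_pct = 100 * mean(hr_est$analyzed),
    n_windows = nrow(hr_est),
    n_scored = sum(scored)
  ), class = "hr_report")
}

# match each estimated beat to its nearest reference beat; a match must lie
# within half the local reference interval, and each reference beat keeps
# only its closest estimate
match_beats <- function(est_t, ref_t) {
  if (!length(est_t) || length(ref_t) < 2) {
    return(rep(NA_integer_, length(est_t)))
  }
  pos <- findInterval(est_t, ref_t)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(ref_t))
  d_lo <- abs(est_t - ref_t[lo])
  d_hi <- abs(est_t - ref_t[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dt <- abs(est_t - ref_t[nearest])
  ibis <- diff(ref_t)
  local_ibi <- vapply(nearest, function(r) {
    adj <- c(if (r > 1) ibis[r - 1], if (r < length(ref_t)) ibis[r])
    min(adj)
  }, numeric(1))
  m <- ifelse(dt <= local_ibi / 2, nearest, NA_integer_)
  # unique assignment: a reference beat keeps only its closest estimate
  for (r in unique(m[!is.na(m)])) {
    dup <- which(!is.na(m) & m == r)
    if (length(dup) > 1) m[dup[-which.min(dt[dup])]] <- NA_integer_
  }
  m
}

#' Beat-level IBI metrics with the 30 ms correctness rule
#'
#' Estimated beats are matched to their nearest reference beats (within half
#' the local reference interval, one estimate per reference beat); an
#' estimated interval is scored when its two endpoints match *consecutive*
#' reference beats. A scored interval is correct when
#' `|RR - JJ| <= tol_ms` (inclusive). Precision is correct over scored;
#' the detection rate divides correct by *all* reference heartbeats,
#' including those in windows the pipeline discarded.
#'
#' @param est a `fused_ibi` object, a per-channel beat data frame (columns
#'   `time_s`, `ibi_ms`), or a numeric vector of beat times (s).
#' @param ref_beats a [beat_annotations()] with at least 2 beats.
#' @param tol_ms correctness tolerance (ms), default 30.
#' @return list of class `ibi_report`: `mae_ms`, `mrae_pct`, `sdae_ms`,
#'   `prec_pct`, `det_pct`, `n_correct`, `n_incorrect`, `n_all_ref_beats`,
#'   `bland_altman` and the paired intervals (`pairs`).
#' @export
ibi_metrics <- function(est, ref_beats, tol_ms = 30) {
  ref_t <- ref_beats$beat_times_s
  if (length(ref_t) < 2) stop("need at least 2 reference beats")
  if (inherits(est, "fused_ibi")) est <- est$beats
  est_t <- if (is.data.frame(est)) est$time_s else as.numeric(est)
  est_ibi <- if (is.data.frame(est) && "ibi_ms" %in% names(est)) {
    est$ibi_ms
  } else {
    c(NA_real_, diff(est_t) * 1000)
  }
  m <- match_beats(est_t, ref_t)
  rr <- numeric(0); jj <- numeric(0)
  if (length(est_t) >= 2) {
    for (k in 2:length(est_t)) {
      if (is.na(est_ibi[k]) || is.na(m[k]) || is.na(m[k - 1])) next
      if (m[k] != m[k - 1] + 1L) next
      rr <- c(rr, (ref_t[m[k]] - ref_t[m[k - 1]]) * 1000)
      jj <- c(jj, est_ibi[k])
    }
  }
  ae <- abs(rr - jj)
  # inclusive threshold with a nanosecond slack against float rounding
  n_correct <- sum(ae <= tol_ms + 1e-9)
  n_incorrect <- length(ae) - n_correct
  ba <- if (length(rr) >= 2) bland_altman(rr, jj) else
    list(bias_ms = NA_real_, loa_low_ms = NA_real_, loa_high_ms = NA_real_)
  structure(list(
    mae_ms = if (length(ae)) mean(ae) else NA_real_,
    mrae_pct = if (length(ae)) mean(ae / rr) * 100 else NA_real_,
    sdae_ms = if (length(ae)) sqrt(mean((ae - mean(ae))^2)) else NA_real_,
    prec_pct = if (length(ae)) 100 * n_correct / length(ae) else NA_real_,
    det_pct = 100 * n_correct / length(ref_t),
    n_correct = n_correct,
    n_incorrect = n_incorrect,
    n_all_ref_beats = length(ref_t),
    bland_altman = ba,
    pairs = data.frame(rr_ms = rr, jj_ms = jj)
  ), class = "ibi_report")
}

#' Bland-Altman agreement of paired intervals
#'
#' Bias is the mean difference `JJ - RR`; the 95% limits of agreement are
#' `bias +/- 1.96 * sd(JJ - RR)`.
#'
#' @param rr_ms,jj_ms paired reference and estimated intervals (ms), length
#'   >= 2.
#' @return list: `bias_ms`, `loa_low_ms`, `loa_high_ms`.
#' @export
bland_altman <- function(rr_ms, jj_ms) {
  stopifnot(length(rr_ms) == length(jj_ms), length(rr_ms) >= 2)
  d <- jj_ms - rr_ms
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias_ms = bias, loa_low_ms = bias - 1.96 * s,
       loa_high_ms = bias + 1.96 * s)
}

#' @export
print.ibi_report <- function(x, ...) {
  cat(sprintf(
    "<ibi_report: MAE %.2f ms, MRAE %.2f%%, SDAE %.2f ms, Prec %.2f%%, Det %.2f%% (%d/%d ref beats)>\n",
    x$mae_ms, x$mrae_pct, x$sdae_ms, x$prec_pct, x$det_pct,
    x$n_correct, x$n_all_ref_beats))
  invisible(x)
}

#' @export
print.hr_report <- function(x, ...) {
  cat(sprintf("<hr_report: MAE %.2f bpm, MRAE %.2f%%, SDAE %.2f bpm, Cov %.2f%%>\n",
              x$mae_bpm, x$mrae_pct, x$sdae_bpm, x$cov_pct))
  invisible(x)
}
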