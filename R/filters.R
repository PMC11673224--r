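# Zero-phase Butterworth band-pass filtering and the band-candidate bank.

# design cache keyed by (order, lo, hi, sr)
.filter_cache <- new.env(parent = emptyenv())

butter_coeffs <- function(order, f_lo, f_hi, sr_hz) {
  key <- paste(order, f_lo, f_hi, sr_hz, sep = "|")
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  ba <- signal::butter(order, c(f_lo, f_hi) / (sr_hz / 2), type = "pass")
  .filter_cache[[key]] <- ba
  ba
}

# forward-backward IIR pass with odd-reflection padding. The pad length is
# scaled to the low cutoff so start-up transients decay below 1e-12 before the
# retained region; this makes the operation time-reversal symmetric to
# numerical precision.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  yp <- as.numeric(signal::filter(b, a, xp))
  yp <- rev(as.numeric(signal::filter(b, a, rev(yp))))
  if (pad > 0) yp <- yp[(pad + 1):(pad + n)]
  yp
}

#' Zero-phase band-pass filter
#'
#' Third-order (by default) Butterworth band-pass applied bidirectionally
#' (forward-backward), giving a zero-phase response: symmetric pulses keep
#' their peak sample, and filtering commutes with time reversal.
#'
#' @param x a [channel_signal()].
#' @param f_lo,f_hi band edges (Hz), `0 < f_lo < f_hi < sr/2`.
#' @param order Butterworth order (the cascade has twice this order).
#' @return a filtered [channel_signal()] of equal length.
#' @export
bandpass_bidirectional <- function(x, f_lo, f_hi, order = 3) {
  stopifnot(inherits(x, "channel_signal"))
  nyq <- x$sr_hz / 2
  if (!(f_lo > 0 && f_lo < f_hi)) stop("require 0 < f_lo < f_hi")
  if (f_hi >= nyq) {
    stop(sprintf(paste0("high cutoff %.3g Hz is at or above the Nyquist ",
                        "frequency %.3g Hz: resample the signal or clamp the ",
                        "cutoff below 0.45 * sr"), f_hi, nyq))
  }
  ba <- butter_coeffs(order, f_lo, f_hi, x$sr_hz)
  pad <- as.integer(ceiling(10 * x$sr_hz / f_lo))
  channel_signal(filtfilt_padded(ba$b, ba$a, x$samples, pad), x$sr_hz, x$label)
}

#' Band weight for a low cutoff
#'
#' `beta = 1 + K * (fL - 1)`: bands with a higher low cutoff carry more of the
#' heart-valve signature and receive a higher weight in the per-beat quality
#' index.
#'
#' @param fl_hz low cutoff (Hz).
#' @param k_weight weighting coefficient K.
#' @return numeric weight, >= 1 for `fl_hz >= 1` and `k_weight >= 0`.
#' @export
band_beta <- function(fl_hz, k_weight) 1 + k_weight * (fl_hz - 1)

#' Build the band-candidate bank for one channel
#'
#' Filters the channel once per candidate low cutoff in
#' `cfg$candidate_fl_hz`, each to `[fL, fH]`, and attaches the band weight.
#' When the sampling rate is too low for the configured high cutoff the
#' cutoff is clamped to `0.45 * sr` with a warning.
#'
#' @param x a [channel_signal()] at least `cfg$window_s` long.
#' @param cfg an [hsf_config()].
#' @return list of `band_candidate` objects (fields `fl_hz`, `fh_hz`, `beta`,
#'   `filtered`).
#' @export
build_band_candidates <- function(x, cfg) {
  if (length(x$samples) < cfg$window_s * x$sr_hz) {
    stop("channel shorter than one analysis window")
  }
  fh <- cfg$fh_hz
  if (fh >= 0.45 * x$sr_hz) {
    fh <- 0.45 * x$sr_hz
    warning(sprintf("high cutoff clamped to %.3g Hz for sr = %g Hz",
                    fh, x$sr_hz))
  }
  out <- list()
  for (fl in cfg$candidate_fl_hz) {
    cand <- tryCatch(
      structure(list(fl_hz = fl, fh_hz = fh,
                     beta = band_beta(fl, cfg$k_weight),
                     filtered = bandpass_bidirectional(x, fl, fh,
                                                       cfg$filter_order)),
                class = "band_candidate"),
      error = function(e) {
        warning(sprintf("band [%g, %g] Hz dropped for '%s': %s",
                        fl, fh, x$label, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(cand)) out[[length(out) + 1]] <- cand
  }
  out
}
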