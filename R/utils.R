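#' Strict local maxima of a numeric series
#'
#' A sample is a local maximum when it is strictly greater than the nearest
#' distinct values on both sides; runs of equal samples (plateaus) count once,
#' at the first sample of the run.
#'
#' @param x numeric vector.
#' @return integer vector of 1-based positions, increasing.
#' @keywords internal
local_maxima <- function(x) {
  r <- rle(as.numeric(x))
  v <- r$values
  k <- length(v)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1L)
  hit <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  starts[i][hit]
}

# z-score; returns NULL when the series is (numerically) constant
zscore_or_null <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(mean(x)))) {
    return(NULL)
  }
  (x - mean(x)) / s
}

# cumulative trapezoid integral on a uniform grid starting at 0
cumtrapz_uniform <- function(y, dx) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2) * dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
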