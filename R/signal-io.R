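#' Single-channel signal container
#'
#' @param samples numeric amplitude series (arbitrary sensor units).
#' @param sr_hz sampling rate (Hz), > 0.
#' @param label sensor name, e.g. `"PEC"`, `"Radar0"`, `"EMFi1"`, `"LC0"`.
#' @return object of class `channel_signal`.
#' @export
channel_signal <- function(samples, sr_hz, label = "ch") {
  stopifnot(is.numeric(samples), length(sr_hz) == 1, sr_hz > 0)
  structure(list(samples = as.numeric(samples), sr_hz = as.numeric(sr_hz),
                 label = as.character(label)),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal '%s': %d samples @ %g Hz (%.2f s)>\n",
              x$label, length(x$samples), x$sr_hz,
              length(x$samples) / x$sr_hz))
  invisible(x)
}

#' Multichannel recording container
#'
#' All channels must share sampling rate and length (resample first
#' otherwise).
#'
#' @param channels list of [channel_signal()] objects.
#' @return object of class `recording`.
#' @export
recording <- function(channels) {
  stopifnot(length(channels) >= 1)
  srs <- vapply(channels, function(ch) ch$sr_hz, numeric(1))
  ns <- vapply(channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(srs)) != 1) stop("channels must share one sampling rate")
  if (length(unique(ns)) != 1) stop("channels must have equal length")
  structure(list(channels = channels, sr_hz = srs[1],
                 duration_s = ns[1] / srs[1]),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channel(s) @ %g Hz, %.2f s>\n",
              length(x$channels), x$sr_hz, x$duration_s))
  for (ch in x$channels) cat("  -", ch$label, "\n")
  invisible(x)
}

#' Keep a subset of channels
#' @param rec a [recording()].
#' @param idx integer or character (label) selection.
#' @return a [recording()].
#' @export
subset_channels <- function(rec, idx) {
  if (is.character(idx)) {
    labs <- vapply(rec$channels, function(ch) ch$label, character(1))
    idx <- match(idx, labs)
    if (anyNA(idx)) stop("unknown channel label")
  }
  recording(rec$channels[idx])
}

#' Read a multichannel recording from delimited text
#'
#' Format: a metadata line `#sr_hz=<rate>`, a header row of channel labels,
#' then one comma-separated row per sample.
#'
#' @param path file path.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*sr_hz\\s*=", first)) {
    stop("format error: missing '#sr_hz=' metadata line")
  }
  sr <- as.numeric(sub("^#\\s*sr_hz\\s*=\\s*", "", first))
  if (!is.finite(sr) || sr <= 0) stop("format error: bad sampling rate")
  dat <- tryCatch(
    utils::read.csv(path, skip = 1, check.names = FALSE),
    error = function(e) stop("format error: ", conditionMessage(e), call. = FALSE)
  )
  if (ncol(dat) < 1 || nrow(dat) < 1) stop("format error: empty recording")
  if (anyNA(dat)) stop("format error: ragged or non-numeric columns")
  chans <- lapply(names(dat), function(nm) channel_signal(dat[[nm]], sr, nm))
  recording(chans)
}

#' Write a multichannel recording as delimited text
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sr_hz=%.10g", rec$sr_hz), con)
  dat <- as.data.frame(lapply(rec$channels, function(ch) ch$samples))
  names(dat) <- vapply(rec$channels, function(ch) ch$label, character(1))
  utils::write.csv(dat, con, row.names = FALSE)
  invisible(path)
}

#' Beat annotations (reference or ground truth)
#'
#' @param beat_times_s strictly increasing beat times (s).
#' @param source label of the annotation source.
#' @return object of class `beat_annotations`.
#' @export
beat_annotations <- function(beat_times_s, source = "reference") {
  t <- as.numeric(beat_times_s)
  if (length(t) && any(diff(t) <= 0)) stop("beat times must be strictly increasing")
  if (length(t) && any(t < 0)) stop("beat times must be non-negative")
  structure(list(beat_times_s = t, source = as.character(source)),
            class = "beat_annotations")
}

#' Read / write beat annotations (CSV with a `beat_time_s` column)
#' @param path file path.
#' @return a [beat_annotations()].
#' @export
read_beats <- function(path) {
  dat <- utils::read.csv(path)
  if (!"beat_time_s" %in% names(dat)) stop("format error: no beat_time_s column")
  src <- if ("source" %in% names(dat) && nrow(dat)) dat$source[1] else "reference"
  beat_annotations(dat$beat_time_s, src)
}

#' @rdname read_beats
#' @param ann a [beat_annotations()].
#' @export
write_beats <- function(ann, path) {
  dat <- data.frame(beat_time_s = ann$beat_times_s,
                    source = rep(ann$source, length(ann$beat_times_s)))
  utils::write.csv(dat, path, row.names = FALSE)
  invisible(path)
}

#' Write a fused IBI series as CSV
#'
#' Columns: `beat_index, time_s, ibi_ms, source_channel, sqi_beat, band_fl_hz`.
#' The first beat has an empty `ibi_ms` (no predecessor).
#'
#' @param result a `fused_ibi` object (see [fuse_sequences()]) or a data frame
#'   with compatible columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ibi_table <- function(result, path) {
  beats <- if (inherits(result, "fused_ibi")) result$beats else result
  dat <- data.frame(
    beat_index = seq_len(nrow(beats)),
    time_s = round(beats$time_s, 6),
    ibi_ms = round(beats$ibi_ms, 6),
    source_channel = beats$source_channel,
    sqi_beat = round(beats$sqi_beat, 6),
    band_fl_hz = beats$band_fl_hz
  )
  utils::write.csv(dat, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an IBI table written by [write_ibi_table()]
#' @param path file path.
#' @return data frame with the written columns.
#' @export
read_ibi_table <- function(path) {
  utils::read.csv(path, colClasses = c(source_channel = "character"))
}

#' Resample a channel with quadratic spline interpolation
#'
#' Fits an interpolating order-2 B-spline through the input samples and
#' evaluates it on the uniform output grid spanning the same time interval
#' (`round(duration * sr_out)` samples). Quadratic splines reproduce
#' polynomials up to degree 2 exactly.
#'
#' @param x a [channel_signal()] with at least 3 samples.
#' @param sr_out output sampling rate (Hz).
#' @return a [channel_signal()] at `sr_out`.
#' @export
resample_quadratic_spline <- function(x, sr_out) {
  stopifnot(inherits(x, "channel_signal"), sr_out > 0)
  y <- x$samples
  n <- length(y)
  if (n < 3) stop("quadratic spline needs at least 3 samples")
  dur <- n / x$sr_hz
  t_in <- (seq_len(n) - 1) / x$sr_hz
  m <- round(dur * sr_out)
  t_out <- (seq_len(m) - 1) / sr_out
  channel_signal(quad_spline_interp(t_in, y, t_out), sr_out, x$label)
}

# order-2 B-spline interpolation on a uniform input grid; output points may
# extend slightly past the last input sample (the recording duration), so the
# data are first extended by two quadratically extrapolated phantom points on
# each side
quad_spline_interp <- function(t_in, y, t_out) {
  h <- t_in[2] - t_in[1]
  lag3 <- function(ts, ys, tt) {
    # quadratic Lagrange polynomial through 3 points
    l1 <- (tt - ts[2]) * (tt - ts[3]) / ((ts[1] - ts[2]) * (ts[1] - ts[3]))
    l2 <- (tt - ts[1]) * (tt - ts[3]) / ((ts[2] - ts[1]) * (ts[2] - ts[3]))
    l3 <- (tt - ts[1]) * (tt - ts[2]) / ((ts[3] - ts[1]) * (ts[3] - ts[2]))
    ys[1] * l1 + ys[2] * l2 + ys[3] * l3
  }
  n <- length(t_in)
  tl <- t_in[1] - c(2, 1) * h
  tr <- t_in[n] + c(1, 2) * h
  X <- c(tl, t_in, tr)
  Y <- c(lag3(t_in[1:3], y[1:3], tl), y,
         lag3(t_in[(n - 2):n], y[(n - 2):n], tr))
  n2 <- length(X)
  knots <- c(rep(X[1], 3), (X[2:(n2 - 2)] + X[3:(n2 - 1)]) / 2, rep(X[n2], 3))
  B <- splines::splineDesign(knots, X, ord = 3, sparse = TRUE)
  coef <- as.numeric(Matrix::solve(B, Y))
  Bo <- splines::splineDesign(knots, t_out, ord = 3, sparse = TRUE)
  as.numeric(Bo %*% coef)
}

#' Decimate a channel by an integer factor
#'
#' Plain decimation (every `factor`-th sample, no anti-alias stage); used by
#' the sampling-rate experiments.
#'
#' @param x a [channel_signal()].
#' @param factor positive integer.
#' @return a [channel_signal()] at `sr_hz / factor`.
#' @export
decimate_channel <- function(x, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  channel_signal(x$samples[seq(1, length(x$samples), by = factor)],
                 x$sr_hz / factor, x$label)
}
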