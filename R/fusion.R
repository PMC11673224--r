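# Beat-level fusion of per-channel detections: align beats across channels
# into chronological slots, then pick, per slot, the channel with the best
# per-beat quality among those whose previous beat was reliable.

#' Align per-channel beats into fused-beat slots
#'
#' Greedy chronological grouping: walking through all channels' beats in time
#' order, a beat joins the current slot when it lies within `tol_s` of the
#' slot's earliest member and its channel is not yet represented; otherwise
#' it opens a new slot.
#'
#' @param sequences named list of per-channel beat data frames (columns
#'   `time_s`, `sqi_beat`, `ibi_ms`, plus any carried metadata).
#' @param tol_s alignment tolerance (s); keep below `(1 - v) * L / SR` so
#'   adjacent beats cannot merge.
#' @return data frame with one row per (slot, channel) membership: `slot`,
#'   `channel`, `time_s`, `sqi_beat`, `ibi_ms`, `fl_hz`.
#' @export
align_beats <- function(sequences, tol_s = 0.15) {
  stopifnot(length(sequences) >= 1)
  rows <- do.call(rbind, lapply(names(sequences), function(nm) {
    b <- sequences[[nm]]
    if (!nrow(b)) return(NULL)
    data.frame(channel = nm, time_s = b$time_s, sqi_beat = b$sqi_beat,
               ibi_ms = b$ibi_ms,
               fl_hz = if ("fl_hz" %in% names(b)) b$fl_hz else NA_real_)
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(data.frame(slot = integer(0), channel = character(0),
                      time_s = numeric(0), sqi_beat = numeric(0),
                      ibi_ms = numeric(0), fl_hz = numeric(0)))
  }
  rows <- rows[order(rows$time_s), , drop = FALSE]
  slot <- integer(nrow(rows))
  cur <- 1L
  slot[1] <- 1L
  anchor <- rows$time_s[1]
  members <- rows$channel[1]
  if (nrow(rows) >= 2) {
    for (i in 2:nrow(rows)) {
      if (rows$time_s[i] - anchor <= tol_s &&
          !(rows$channel[i] %in% members)) {
        slot[i] <- cur
        members <- c(members, rows$channel[i])
      } else {
        cur <- cur + 1L
        slot[i] <- cur
        anchor <- rows$time_s[i]
        members <- rows$channel[i]
      }
    }
  }
  rows$slot <- slot
  rows[, c("slot", "channel", "time_s", "sqi_beat", "ibi_ms", "fl_hz")]
}

#' Fuse aligned beats into one IBI series
#'
#' Per slot, channels present in both this slot and the previous one with a
#' previous-beat quality above `theta_beat` are eligible; the eligible
#' channel with the highest current quality supplies the fused beat. When no
#' channel is eligible (including the very first slot) the best present
#' channel is used and the beat is flagged low-confidence. Fused intervals
#' are differences of consecutive fused beat times, so switching source
#' channels cannot double-count inter-sensor offsets; the source channel's
#' internal interval is carried alongside for audit.
#'
#' @param slots output of [align_beats()].
#' @param cfg an [hsf_config()].
#' @return object of class `fused_ibi` with `$beats`: `time_s`, `ibi_ms`,
#'   `source_channel`, `sqi_beat`, `band_fl_hz`, `channel_ibi_ms`,
#'   `low_confidence`.
#' @export
fuse_slots <- function(slots, cfg) {
  if (!nrow(slots)) {
    beats <- data.frame(time_s = numeric(0), ibi_ms = numeric(0),
                        source_channel = character(0), sqi_beat = numeric(0),
                        band_fl_hz = numeric(0), channel_ibi_ms = numeric(0),
                        low_confidence = logical(0))
    return(structure(list(beats = beats), class = "fused_ibi"))
  }
  ids <- sort(unique(slots$slot))
  prev_sqi <- NULL  # named per-channel sqi of the previous slot
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    cur <- slots[slots$slot == ids[j], , drop = FALSE]
    eligible <- if (!is.null(prev_sqi)) {
      cur$channel[cur$channel %in% names(prev_sqi) &
                    prev_sqi[cur$channel] > cfg$theta_beat]
    } else character(0)
    lowconf <- !length(eligible)
    pool <- if (lowconf) cur else cur[cur$channel %in% eligible, ,
                                      drop = FALSE]
    k <- which.max(pool$sqi_beat)
    out[[j]] <- data.frame(time_s = pool$time_s[k],
                           source_channel = pool$channel[k],
                           sqi_beat = pool$sqi_beat[k],
                           band_fl_hz = pool$fl_hz[k],
                           channel_ibi_ms = pool$ibi_ms[k],
                           low_confidence = lowconf)
    prev_sqi <- stats::setNames(cur$sqi_beat, cur$channel)
  }
  beats <- do.call(rbind, out)
  beats$ibi_ms <- c(NA_real_, diff(beats$time_s) * 1000)
  beats <- beats[, c("time_s", "ibi_ms", "source_channel", "sqi_beat",
                     "band_fl_hz", "channel_ibi_ms", "low_confidence")]
  structure(list(beats = beats), class = "fused_ibi")
}

#' Align and fuse per-channel beat sequences
#'
#' Convenience wrapper chaining [align_beats()] and [fuse_slots()].
#'
#' @param sequences named list of per-channel beat data frames.
#' @param cfg an [hsf_config()].
#' @return a `fused_ibi` object.
#' @export
fuse_sequences <- function(sequences, cfg) {
  fuse_slots(align_beats(sequences, cfg$align_tol_s), cfg)
}

#' @export
print.fused_ibi <- function(x, ...) {
  b <- x$beats
  cat(sprintf("<fused_ibi: %d beats", nrow(b)))
  if (nrow(b) > 1) {
    cat(sprintf(", median IBI %.0f ms, sources: %s",
                stats::median(b$ibi_ms, na.rm = TRUE),
                paste(unique(b$source_channel), collapse = ", ")))
  }
  cat(">\n")
  invisible(x)
}
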