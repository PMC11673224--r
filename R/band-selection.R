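# Per-channel optimal band selection and channel admission from the
# window-level quality index.

#' Select the operating band of one channel
#'
#' Three-clause rule over the per-band quality table of one channel/window:
#' \enumerate{
#'   \item if any band has SQI > Q1, keep the highest low cutoff among those;
#'   \item else if any band has SQI > Q2, keep the band with the maximal SQI
#'     (ties break toward the higher cutoff);
#'   \item else discard the channel for this window.
#' }
#'
#' @param sqi_by_fl named numeric vector: names are low cutoffs (Hz), values
#'   the window quality index of that band.
#' @param cfg an [hsf_config()].
#' @return list of class `band_decision`: `status` ("selected"/"discarded"),
#'   `fl_hz`, `beta`, `sqi`, `rule` (1, 2 or 3).
#' @export
#' @examples
#' cfg <- hsf_config()
#' select_band(c(`1` = 0.6, `3` = 0.55, `5` = 0.3, `7` = 0.2), cfg)
select_band <- function(sqi_by_fl, cfg) {
  stopifnot(length(sqi_by_fl) >= 1)
  fl <- as.numeric(names(sqi_by_fl))
  sqi <- as.numeric(sqi_by_fl)
  ord <- order(fl)
  fl <- fl[ord]; sqi <- sqi[ord]
  dec <- function(status, fl_hz = NA_real_, sqi_v = NA_real_, rule) {
    structure(list(status = status, fl_hz = fl_hz,
                   beta = if (is.na(fl_hz)) NA_real_
                          else band_beta(fl_hz, cfg$k_weight),
                   sqi = sqi_v, rule = rule),
              class = "band_decision")
  }
  over_q1 <- which(sqi > cfg$q1)
  if (length(over_q1)) {
    k <- over_q1[length(over_q1)]  # highest fL passing Q1
    return(dec("selected", fl[k], sqi[k], 1L))
  }
  over_q2 <- which(sqi > cfg$q2)
  if (length(over_q2)) {
    best <- max(sqi[over_q2])
    cand <- over_q2[sqi[over_q2] == best]
    k <- cand[length(cand)]        # tie toward higher band
    return(dec("selected", fl[k], sqi[k], 2L))
  }
  dec("discarded", rule = 3L)
}

#' Admit channels from their band decisions
#'
#' @param decisions named list of `band_decision` objects, one per channel
#'   (names are channel labels).
#' @return data frame of admitted channels (`channel`, `fl_hz`, `beta`,
#'   `sqi`, `rule`); zero rows when every channel is discarded, in which case
#'   the window counts as uncovered.
#' @export
admit_channels <- function(decisions) {
  keep <- vapply(decisions, function(d) d$status == "selected", logical(1))
  if (!any(keep)) {
    return(data.frame(channel = character(0), fl_hz = numeric(0),
                      beta = numeric(0), sqi = numeric(0), rule = integer(0)))
  }
  sel <- decisions[keep]
  data.frame(
    channel = names(sel),
    fl_hz = vapply(sel, function(d) d$fl_hz, numeric(1)),
    beta = vapply(sel, function(d) d$beta, numeric(1)),
    sqi = vapply(sel, function(d) d$sqi, numeric(1)),
    rule = vapply(sel, function(d) d$rule, integer(1)),
    row.names = NULL
  )
}
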