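#' Pipeline configuration
#'
#' Builds the validated set of hyperparameters shared by every stage of the
#' IBI-extraction pipeline. All defaults are the published operating point of
#' the method; they are deliberately subject-independent.
#'
#' @param candidate_fl_hz ordered candidate low cutoffs of the band-selection
#'   filter bank (Hz). Default `c(1, 3, 5, 7)`.
#' @param fh_hz fixed high cutoff of the filter bank (Hz). Default 40.
#' @param k_weight band weighting coefficient K; the weight of the band with
#'   low cutoff fL is `beta = 1 + K * (fL - 1)`. Default 0.05.
#' @param q1,q2 upper and lower thresholds on the window-level spectral
#'   signal-quality index. Defaults 0.52 and 0.26.
#' @param theta_bsas correlation threshold of the sequential (BSAS) segment
#'   clustering. Default 0.75.
#' @param theta_beat acceptance threshold on the per-beat quality index.
#'   Default 0.75. Stored separately from `theta_bsas` although both default
#'   to the same published value, so either can be tuned alone.
#' @param v_hrv half-width of the beat search window as a fraction of the
#'   expected beat period (short-term HRV allowance). Default 0.3.
#' @param window_s,step_s analysis window length and hop (s). Defaults 8 and 1.
#' @param harsum_band_hz passband of the harmonic-summation preprocessing
#'   filter (Hz). Default `c(1, 10)`.
#' @param hr_search_bpm candidate heart-rate range for the fundamental search
#'   (bpm). Default `c(42, 180)`.
#' @param max_harmonics largest harmonic order entering the summation kernel.
#'   Default 7.
#' @param harmonic_set multipliers used by the kernel. Default `c(1, 2, 3, 5, 7)`.
#' @param consecutive_low_sqi_for_update number of consecutive low-quality
#'   beats that triggers a template update. Default 5.
#' @param filter_order Butterworth order of all band-pass filters. Default 3.
#' @param f0_grid_step_hz spacing of the candidate fundamental grid (Hz).
#'   Default 0.005 (0.3 bpm).
#' @param fft_pad_factor zero-padding factor of the window FFT. Default 8.
#' @param harmonic_aperture_hz width of the spectral aperture over which
#'   harmonic/valley mass is integrated (Hz). Default 0.25.
#' @param edge_trim_s filtered-signal margin excluded from peak detection at
#'   the recording edges (s). Default 0.5.
#' @param max_consecutive_misses missed-beat count that forces a template
#'   update. Default 3.
#' @param align_tol_s cross-channel beat alignment tolerance for fusion (s).
#'   Default 0.15.
#' @param cluster_rank rule ranking segment clusters when picking the primary
#'   template: `"center"` (mean center-sample amplitude) or `"l2norm"`
#'   (mean member L2 norm).
#'
#' @return an object of class `hsf_config` (a validated named list).
#' @export
#' @examples
#' cfg <- hsf_config()
#' cfg$q1
hsf_config <- function(candidate_fl_hz = c(1, 3, 5, 7),
                       fh_hz = 40,
                       k_weight = 0.05,
                       q1 = 0.52,
                       q2 = 0.26,
                       theta_bsas = 0.75,
                       theta_beat = 0.75,
                       v_hrv = 0.3,
                       window_s = 8,
                       step_s = 1,
                       harsum_band_hz = c(1, 10),
                       hr_search_bpm = c(42, 180),
                       max_harmonics = 7,
                       harmonic_set = c(1, 2, 3, 5, 7),
                       consecutive_low_sqi_for_update = 5,
                       filter_order = 3,
                       f0_grid_step_hz = 0.005,
                       fft_pad_factor = 8,
                       harmonic_aperture_hz = 0.25,
                       edge_trim_s = 0.5,
                       max_consecutive_misses = 3,
                       align_tol_s = 0.15,
                       cluster_rank = c("center", "l2norm")) {
  cfg <- list(
    candidate_fl_hz = as.numeric(candidate_fl_hz),
    fh_hz = as.numeric(fh_hz),
    k_weight = as.numeric(k_weight),
    q1 = as.numeric(q1),
    q2 = as.numeric(q2),
    theta_bsas = as.numeric(theta_bsas),
    theta_beat = as.numeric(theta_beat),
    v_hrv = as.numeric(v_hrv),
    window_s = as.numeric(window_s),
    step_s = as.numeric(step_s),
    harsum_band_hz = as.numeric(harsum_band_hz),
    hr_search_bpm = as.numeric(hr_search_bpm),
    max_harmonics = as.numeric(max_harmonics),
    harmonic_set = as.numeric(harmonic_set),
    consecutive_low_sqi_for_update = as.numeric(consecutive_low_sqi_for_update),
    filter_order = as.numeric(filter_order),
    f0_grid_step_hz = as.numeric(f0_grid_step_hz),
    fft_pad_factor = as.numeric(fft_pad_factor),
    harmonic_aperture_hz = as.numeric(harmonic_aperture_hz),
    edge_trim_s = as.numeric(edge_trim_s),
    max_consecutive_misses = as.numeric(max_consecutive_misses),
    align_tol_s = as.numeric(align_tol_s),
    cluster_rank = match.arg(cluster_rank)
  )
  class(cfg) <- "hsf_config"
  validate_hsf_config(cfg)
  cfg
}

#' Validate a configuration object
#'
#' @param cfg an `hsf_config`.
#' @return `cfg`, invisibly, when every invariant holds; otherwise an error
#'   naming the violated invariant.
#' @export
validate_hsf_config <- function(cfg) {
  fail <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  fl <- cfg$candidate_fl_hz
  if (length(fl) < 1 || any(!is.finite(fl))) fail("candidate_fl_hz must be non-empty and finite")
  if (length(fl) > 1 && any(diff(fl) <= 0)) fail("candidate_fl_hz must be strictly increasing")
  if (any(fl <= 0) || any(fl >= cfg$fh_hz)) fail("candidate_fl_hz must satisfy 0 < fL < fh_hz")
  if (!(cfg$q2 > 0 && cfg$q1 > cfg$q2 && cfg$q1 < 1)) fail("thresholds must satisfy 0 < q2 < q1 < 1")
  if (!(cfg$theta_bsas > 0 && cfg$theta_bsas < 1)) fail("theta_bsas must lie in (0, 1)")
  if (!(cfg$theta_beat > 0 && cfg$theta_beat < 1)) fail("theta_beat must lie in (0, 1)")
  if (!(cfg$v_hrv > 0 && cfg$v_hrv < 1)) fail("v_hrv must lie in (0, 1)")
  if (!(cfg$step_s > 0 && cfg$window_s >= cfg$step_s)) fail("window_s >= step_s > 0 required")
  if (cfg$max_harmonics > 7) fail("max_harmonics must be <= 7")
  if (any(cfg$harmonic_set > cfg$max_harmonics)) fail("harmonic_set members must be <= max_harmonics")
  if (!(length(cfg$harsum_band_hz) == 2 && cfg$harsum_band_hz[1] > 0 &&
        cfg$harsum_band_hz[1] < cfg$harsum_band_hz[2])) fail("harsum_band_hz must be an increasing pair")
  if (!(length(cfg$hr_search_bpm) == 2 && cfg$hr_search_bpm[1] > 0 &&
        cfg$hr_search_bpm[1] < cfg$hr_search_bpm[2])) fail("hr_search_bpm must be an increasing pair")
  if (cfg$k_weight < 0) fail("k_weight must be >= 0")
  if (cfg$filter_order < 1) fail("filter_order must be >= 1")
  if (cfg$fft_pad_factor < 1) fail("fft_pad_factor must be >= 1")
  if (cfg$f0_grid_step_hz <= 0) fail("f0_grid_step_hz must be > 0")
  if (cfg$harmonic_aperture_hz <= 0) fail("harmonic_aperture_hz must be > 0")
  if (cfg$consecutive_low_sqi_for_update < 1) fail("consecutive_low_sqi_for_update must be >= 1")
  if (cfg$max_consecutive_misses < 1) fail("max_consecutive_misses must be >= 1")
  if (cfg$align_tol_s <= 0) fail("align_tol_s must be > 0")
  if (cfg$edge_trim_s < 0) fail("edge_trim_s must be >= 0")
  invisible(cfg)
}

#' Load a configuration from a JSON file
#'
#' Fields absent from the file take their defaults; `overrides` are applied on
#' top of the file contents. Unknown keys (in the file or the overrides) are a
#' configuration error.
#'
#' @param path path of a JSON file; may hold any subset of [hsf_config()]
#'   fields. An empty object yields the default configuration.
#' @param overrides named list applied after the file.
#' @return validated `hsf_config`.
#' @export
load_config <- function(path, overrides = list()) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  merged <- utils::modifyList(as.list(raw), as.list(overrides))
  known <- names(formals(hsf_config))
  unknown <- setdiff(names(merged), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(hsf_config, merged)
}

#' Write a configuration to a JSON file
#'
#' The written file round-trips through [load_config()] bit-exactly.
#'
#' @param cfg an `hsf_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_hsf_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.hsf_config <- function(x, ...) {
  cat("<hsf_config>\n")
  cat("  bands: fL in {", paste(x$candidate_fl_hz, collapse = ", "),
      "} Hz, fH =", x$fh_hz, "Hz, K =", x$k_weight, "\n")
  cat("  SQI thresholds: Q1 =", x$q1, " Q2 =", x$q2,
      " theta(BSAS) =", x$theta_bsas, " theta(beat) =", x$theta_beat, "\n")
  cat("  window:", x$window_s, "s /", x$step_s, "s step; HR search",
      x$hr_search_bpm[1], "-", x$hr_search_bpm[2], "bpm; v =", x$v_hrv, "\n")
  invisible(x)
}

# Derived quantities used across modules ------------------------------------

# candidate fundamental grid (Hz)
f0_grid <- function(cfg) {
  lo <- cfg$hr_search_bpm[1] / 60
  hi <- cfg$hr_search_bpm[2] / 60
  seq(lo, hi, by = cfg$f0_grid_step_hz)
}

# spectral analysis band for the quality index (Hz)
analysis_band <- function(cfg, sr_hz) {
  c(0.5, min(cfg$max_harmonics * cfg$hr_search_bpm[2] / 60, 0.95 * sr_hz / 2))
}
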