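# Shared fixtures and small oracles for the test suite. Everything is built
# in code at test time; no stored data.

default_cfg <- hsf_config()

# a hand-built amplitude spectrum on a uniform grid (for kernel/summation
# tests independent of any FFT)
make_spec <- function(freqs, amps, band = c(0.5, max(freqs))) {
  df <- freqs[2] - freqs[1]
  structure(list(freqs_hz = freqs, amps = amps, band = band,
                 cum = c(0, cumsum((amps[-1] + amps[-length(amps)]) / 2) * df),
                 df = df),
            class = "amplitude_spectrum")
}

# best absolute correlation over integer lags (alignment-free shape match)
maxlag_cor <- function(a, b, max_lag = 40) {
  n <- min(length(a), length(b))
  a <- a[1:n]; b <- b[1:n]
  best <- -1
  for (lag in -max_lag:max_lag) {
    ia <- max(1, 1 + lag):min(n, n + lag)
    if (length(ia) <= n / 2) next
    r <- suppressWarnings(stats::cor(a[ia], b[ia - lag]))
    if (is.finite(r)) best <- max(best, abs(r))
  }
  best
}

# independent transliteration of sequential clustering for the oracle
# comparison: recomputes the admission score per step from scratch
bsas_oracle <- function(corr, theta) {
  n <- nrow(corr)
  assign <- integer(n)
  assign[1] <- 1L
  for (i in seq_len(n)[-1]) {
    existing <- unique(assign[seq_len(i - 1)])
    scores <- sapply(existing, function(cl) {
      mem <- which(assign[seq_len(i - 1)] == cl)
      min(sapply(mem, function(j) corr[i, j]))
    })
    best <- which.max(scores)
    assign[i] <- if (scores[best] < theta) max(existing) + 1L
                 else existing[best]
  }
  assign
}

# exhaustive primary-cluster / template selection oracle
primary_oracle <- function(segments, assign, corr, rule, restrict = NULL) {
  ids <- sort(unique(assign))
  if (!is.null(restrict)) ids <- intersect(ids, restrict)
  vals <- sapply(ids, function(id) {
    mem <- which(assign == id)
    if (rule == "l2norm") {
      mean(sapply(mem, function(j) sqrt(sum(segments[, j]^2))))
    } else {
      ctr <- floor(nrow(segments) / 2) + 1
      mean(sapply(mem, function(j) segments[ctr, j]))
    }
  })
  cs <- ids[which.max(vals)]
  mem <- which(assign == cs)
  if (length(mem) == 1) return(list(cluster = cs, template = mem))
  sums <- sapply(mem, function(j) sum(sapply(setdiff(mem, j),
                                             function(k) corr[j, k])))
  list(cluster = cs, template = mem[which.max(sums)])
}

# direct gap test / second-template oracle
second_oracle <- function(segments, p_index, assign, corr, cs, L, rule) {
  mem_ctr <- sort(p_index[assign == cs])
  if (length(mem_ctr) < 2) return(NULL)
  in_gap <- rep(FALSE, length(p_index))
  found <- FALSE
  for (h in seq_len(length(mem_ctr) - 1)) {
    if (mem_ctr[h + 1] - mem_ctr[h] > 1.5 * L) {
      found <- TRUE
      in_gap <- in_gap | (p_index > mem_ctr[h] & p_index < mem_ctr[h + 1])
    }
  }
  if (!found) return(NULL)
  cand <- setdiff(unique(assign[in_gap]), cs)
  if (!length(cand)) return(NULL)
  primary_oracle(segments, assign, corr, rule, restrict = cand)
}

# simple periodic test signal: unit-amplitude raised-cosine pulse train
pulse_train <- function(f0_hz, sr_hz, dur_s, width_s = 0.12, phase_s = 0) {
  t <- (0:(round(dur_s * sr_hz) - 1)) / sr_hz
  y <- numeric(length(t))
  beats <- seq(phase_s, dur_s, by = 1 / f0_hz)
  for (tb in beats) {
    idx <- which(abs(t - tb) < width_s / 2)
    y[idx] <- y[idx] + 0.5 * (1 + cos(2 * pi * (t[idx] - tb) / width_s))
  }
  y
}
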