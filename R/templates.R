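# Template-group extraction: segment the first analysis window at its local
# maxima, cluster the segments sequentially (BSAS), and pick one beat
# prototype per morphology (up to two, covering the two respiratory phases).

#' Template length from the mean heart rate
#'
#' `L = round(60 / HR * SR)` samples, i.e. one expected beat period;
#' rounding is round-half-to-even.
#'
#' @param hr_mean_bpm mean heart rate (bpm), > 0.
#' @param sr_hz sampling rate (Hz).
#' @return integer number of samples.
#' @export
#' @examples
#' template_length(60, 1000)  # 1000
#' template_length(75, 250)   # 200
template_length <- function(hr_mean_bpm, sr_hz) {
  stopifnot(hr_mean_bpm > 0, sr_hz > 0)
  as.integer(round(60 / hr_mean_bpm * sr_hz))
}

#' Extract peak-centered segments from a window
#'
#' One segment per strict local maximum whose centered window of length `L`
#' (`[p - floor(L/2), p + ceiling(L/2))`) fits inside the input; boundary
#' maxima are skipped. Plateaus count once, at their first sample.
#'
#' @param s numeric vector (one analysis window of the band-filtered signal).
#' @param L segment length (samples).
#' @return list with `segments` (L x N matrix, one column per segment) and
#'   `p_index` (1-based center positions within `s`). Errors when no interior
#'   maximum exists (channel unusable for this window).
#' @export
extract_segments <- function(s, L) {
  stopifnot(L >= 2, length(s) >= L)
  half_lo <- floor(L / 2)
  half_hi <- ceiling(L / 2)
  pk <- local_maxima(s)
  pk <- pk[pk - half_lo >= 1 & pk + half_hi - 1 <= length(s)]
  if (!length(pk)) stop("no usable local maxima in segment window")
  seg <- vapply(pk, function(p) s[(p - half_lo):(p + half_hi - 1)],
                numeric(L))
  list(segments = matrix(seg, nrow = L), p_index = pk)
}

#' Pearson correlation matrix of segments
#'
#' Symmetric with unit diagonal; rows of zero-variance segments are defined
#' as 0 off the diagonal.
#'
#' @param segments L x N matrix (one segment per column).
#' @return N x N correlation matrix.
#' @export
correlation_matrix <- function(segments) {
  stopifnot(ncol(segments) >= 2)
  cm <- suppressWarnings(stats::cor(segments))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  cm
}

#' Sequential (BSAS) clustering of segments
#'
#' One pass in temporal order: each segment joins the cluster maximizing its
#' minimum correlation to the cluster's members, or opens a new cluster when
#' that maximum falls below `theta`. The result is order-dependent by design.
#'
#' @param corr segment correlation matrix.
#' @param theta admission threshold in (0, 1).
#' @return integer vector of cluster ids (1-based, in order of creation).
#' @export
bsas_cluster <- function(corr, theta) {
  n <- nrow(corr)
  assign <- integer(n)
  assign[1] <- 1L
  m <- 1L
  members <- list(1L)
  if (n >= 2) {
    for (i in 2:n) {
      score <- vapply(members, function(mem) min(corr[i, mem]), numeric(1))
      k <- which.max(score)
      if (score[k] < theta) {
        m <- m + 1L
        members[[m]] <- i
        assign[i] <- m
      } else {
        members[[k]] <- c(members[[k]], i)
        assign[i] <- k
      }
    }
  }
  assign
}

# ranking statistic of a cluster for primary-template selection
cluster_rank_value <- function(segments, members, rule) {
  if (rule == "l2norm") {
    mean(sqrt(colSums(segments[, members, drop = FALSE]^2)))
  } else {
    center <- floor(nrow(segments) / 2) + 1
    mean(segments[center, members])
  }
}

#' Select the primary cluster and template
#'
#' The primary cluster maximizes the configured ranking statistic (mean
#' center-sample amplitude by default, or mean member L2 norm); within it the
#' template is the member with the highest correlation sum to the other
#' members. Ties break toward the earliest cluster / earliest segment.
#'
#' @param segments L x N segment matrix.
#' @param assign cluster ids from [bsas_cluster()].
#' @param corr segment correlation matrix.
#' @param cluster_rank `"center"` or `"l2norm"`.
#' @param restrict optional integer vector of cluster ids to choose among.
#' @return list: `cluster` (id), `template` (segment index).
#' @export
select_primary <- function(segments, assign, corr,
                           cluster_rank = "center", restrict = NULL) {
  ids <- sort(unique(assign))
  if (!is.null(restrict)) ids <- ids[ids %in% restrict]
  stopifnot(length(ids) >= 1)
  vals <- vapply(ids, function(id)
    cluster_rank_value(segments, which(assign == id), cluster_rank),
    numeric(1))
  cs <- ids[which.max(vals)]
  mem <- which(assign == cs)
  if (length(mem) == 1) return(list(cluster = cs, template = mem))
  sums <- vapply(mem, function(j) sum(corr[j, setdiff(mem, j)]), numeric(1))
  list(cluster = cs, template = mem[which.max(sums)])
}

#' Second template from the complementary morphology
#'
#' If consecutive member centers of the primary cluster leave a gap wider
#' than `1.5 * L`, the centers of all other segments falling inside such gaps
#' are collected; clusters (other than the primary) owning at least one such
#' center compete, and the primary-selection rule applied to that restricted
#' set yields the second template. Returns `NULL` when the gap condition is
#' unmet or no competing cluster exists.
#'
#' @param segments L x N segment matrix.
#' @param p_index segment center positions.
#' @param assign cluster ids.
#' @param corr correlation matrix.
#' @param cs primary cluster id.
#' @param L template length (samples).
#' @param cluster_rank ranking rule, as in [select_primary()].
#' @return list (`cluster`, `template`) or `NULL`.
#' @export
second_template <- function(segments, p_index, assign, corr, cs, L,
                            cluster_rank = "center") {
  mem <- which(assign == cs)
  ctr <- sort(p_index[mem])
  if (length(ctr) < 2) return(NULL)
  gaps <- which(diff(ctr) > 1.5 * L)
  if (!length(gaps)) return(NULL)
  gamma <- logical(length(p_index))
  for (g in gaps) {
    gamma <- gamma | (p_index > ctr[g] & p_index < ctr[g + 1])
  }
  cand_clusters <- setdiff(unique(assign[gamma]), cs)
  if (!length(cand_clusters)) return(NULL)
  select_primary(segments, assign, corr, cluster_rank,
                 restrict = cand_clusters)
}

#' Build the template group of one channel
#'
#' Orchestrates segmentation, sequential clustering, and primary/secondary
#' template selection on one analysis window of the selected band.
#'
#' @param s numeric vector: the analysis window (band-filtered).
#' @param hr_mean_bpm mean heart rate guiding the template length (bpm).
#' @param sr_hz sampling rate (Hz).
#' @param cfg an [hsf_config()].
#' @return object of class `template_group`: `templates` (L x k matrix,
#'   k in {1, 2}), `L`, `p_index` (template center positions), `n_clusters`,
#'   `assign`.
#' @export
build_template_group <- function(s, hr_mean_bpm, sr_hz, cfg) {
  L <- template_length(hr_mean_bpm, sr_hz)
  ex <- extract_segments(s, L)
  n <- ncol(ex$segments)
  if (n == 1) {
    return(structure(list(templates = ex$segments, L = L,
                          p_index = ex$p_index, n_clusters = 1L,
                          assign = 1L),
                     class = "template_group"))
  }
  corr <- correlation_matrix(ex$segments)
  assign <- bsas_cluster(corr, cfg$theta_bsas)
  prim <- select_primary(ex$segments, assign, corr, cfg$cluster_rank)
  sec <- second_template(ex$segments, ex$p_index, assign, corr,
                         prim$cluster, L, cfg$cluster_rank)
  idx <- c(prim$template, if (!is.null(sec)) sec$template)
  structure(list(templates = ex$segments[, idx, drop = FALSE], L = L,
                 p_index = ex$p_index[idx],
                 n_clusters = length(unique(assign)), assign = assign),
            class = "template_group")
}

#' @export
print.template_group <- function(x, ...) {
  cat(sprintf("<template_group: %d template(s) of length %d (%d cluster(s))>\n",
              ncol(x$templates), x$L, x$n_clusters))
  invisible(x)
}
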