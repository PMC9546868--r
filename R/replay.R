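#' Frame-by-frame correlation of a task pattern with rest activity
#'
#' Pearson correlation of a spatial pattern with every retained rest frame
#' (restricted to the ROI vertices), pooled across a phase's runs in
#' acquisition order.
#'
#' @param pattern numeric vector over the ROI vertices.
#' @param rest_runs list of preprocessed [vertex_ts()] rest runs.
#' @param roi vertex indices or [select_roi()] result.
#' @return object of class `frame_similarity`: `r` (one value per frame) and
#'   `provenance` (data.frame `run_id`, `frame` 0-based).
#' @export
frame_pattern_correlations <- function(pattern, rest_runs, roi) {
  roi <- roi_indices(roi)
  pattern <- as.numeric(pattern)
  stopifnot(length(pattern) == length(roi))
  if (stats::sd(pattern) < .Machine$double.eps^0.5)
    stop("zero-variance pattern; correlation undefined", call. = FALSE)
  r <- c(); run_id <- c(); frame <- c()
  for (ts in rest_runs) {
    rr <- as.vector(stats::cor(pattern, ts$data[roi, , drop = FALSE]))
    r <- c(r, rr)
    run_id <- c(run_id, rep(ts$run_id, length(rr)))
    frame <- c(frame, seq_along(rr) - 1L)
  }
  structure(list(r = r,
                 provenance = data.frame(run_id = run_id, frame = frame,
                                         stringsAsFactors = FALSE)),
            class = "frame_similarity")
}

#' Empirical-CDF percentile cutoff of pattern-similarity values
#'
#' The headline similarity statistic: the value at the given percentile of the
#' empirical cumulative distribution of transformed correlations. The
#' transform is `r^2` (`"r2"`, also used for spatio-temporal windows), the
#' identity (`"r"`), or sign inversion (`"neg_r"`, equivalent to reading the
#' lower tail of the r distribution). The empirical quantile interpolates
#' linearly between order statistics at position `h = (n - 1) * percentile`.
#'
#' @param r_values numeric vector of Pearson correlations (at least 10).
#' @param variant one of `"r2"`, `"r"`, `"neg_r"`.
#' @param percentile quantile level in (0, 1); default 0.90.
#' @return the cutoff value (scalar).
#' @export
cdf_cutoff <- function(r_values, variant = c("r2", "r", "neg_r"),
                       percentile = 0.90) {
  variant <- match.arg(variant)
  r_values <- as.numeric(r_values)
  if (length(r_values) < 10L)
    stop("need at least 10 values for a stable percentile cutoff", call. = FALSE)
  if (anyNA(r_values)) stop("r_values contain NA", call. = FALSE)
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must be in (0, 1)", call. = FALSE)
  v <- switch(variant, r2 = r_values^2, r = r_values, neg_r = -r_values)
  v <- sort(v)
  idx <- 1 + (length(v) - 1) * percentile
  lo <- floor(idx)
  hi <- ceiling(idx)
  if (idx == lo || v[hi] == v[lo]) return(v[lo])
  g <- idx - lo
  (1 - g) * v[lo] + g * v[hi]
}

#' Sliding spatio-temporal rest windows
#'
#' Extracts every window of `floor(window_s / TR)` consecutive retained frames
#' within each rest run (windows never span runs), flattened vertex-major to
#' match the task spatio-temporal pattern layout (vertex v of window frame k
#' at position `(k-1) * |roi| + v`). Runs shorter than the window are skipped
#' with a warning.
#'
#' @param rest_runs list of preprocessed [vertex_ts()] rest runs.
#' @param roi vertex indices or [select_roi()] result.
#' @param window_s window length in seconds (default 8).
#' @param stride_frames step between window starts (default 1 = maximal
#'   overlap).
#' @return matrix with one column per window (`|roi| * window_frames` rows),
#'   with attribute `provenance` (data.frame `run_id`, `start_frame` 0-based).
#' @export
spatiotemporal_windows <- function(rest_runs, roi, window_s = 8,
                                   stride_frames = 1) {
  roi <- roi_indices(roi)
  assert_count(stride_frames)
  cols <- list(); run_id <- c(); start <- c()
  for (ts in rest_runs) {
    wf <- floor(window_s / ts$tr_seconds)
    nf <- n_frames(ts)
    if (nf < wf) {
      warning(sprintf("run '%s' shorter than window; skipped", ts$run_id),
              call. = FALSE)
      next
    }
    starts <- seq.int(1L, nf - wf + 1L, by = stride_frames)
    sub <- ts$data[roi, , drop = FALSE]
    for (s in starts)
      cols[[length(cols) + 1L]] <- as.vector(sub[, s:(s + wf - 1L)])
    run_id <- c(run_id, rep(ts$run_id, length(starts)))
    start <- c(start, starts - 1L)
  }
  if (!length(cols)) stop("no rest run long enough for the window", call. = FALSE)
  out <- do.call(cbind, cols)
  attr(out, "provenance") <- data.frame(run_id = run_id, start_frame = start,
                                        stringsAsFactors = FALSE)
  out
}

#' Per-subject table of CDF percentile cutoffs
#'
#' Computes the cutoff statistic for every movement x rest phase x variant
#' cell. Spatial variants (`r2`, `r`, `neg_r`) correlate the mean spatial
#' pattern with each rest frame; the `spatiotemporal_r2` variant correlates
#' the concatenated window pattern with every sliding rest window of the same
#' length, then takes the `r^2` cutoff. Rest frames are pooled across each
#' phase's runs before the CDF.
#'
#' @param rest_pre,rest_post lists of preprocessed [vertex_ts()] rest runs
#'   (either may be `NULL`; its cells are omitted with a warning).
#' @param patterns a [compute_mean_patterns()] result.
#' @param roi vertex indices or [select_roi()] result.
#' @param percentile CDF level (default 0.90).
#' @param variants subset of `c("r2", "r", "neg_r", "spatiotemporal_r2")`.
#' @param stride_frames stride of the spatio-temporal sliding window.
#' @param subject subject identifier for the output rows.
#' @return data.frame (`subject`, `movement`, `phase`, `variant`, `cutoff`,
#'   `n_frames`).
#' @export
replay_summary <- function(rest_pre, rest_post, patterns, roi,
                           percentile = 0.90,
                           variants = c("r2", "r", "neg_r", "spatiotemporal_r2"),
                           stride_frames = 1, subject = "sub-01") {
  stopifnot(inherits(patterns, "movement_patterns"))
  variants <- match.arg(variants, several.ok = TRUE)
  roi <- roi_indices(roi)
  phases <- list(pre = rest_pre, post = rest_post)
  rows <- list()
  for (phase in names(phases)) {
    runs <- phases[[phase]]
    if (is.null(runs) || !length(runs)) {
      warning("no ", phase, "-task rest runs; cells omitted", call. = FALSE)
      next
    }
    spatial_vars <- intersect(variants, c("r2", "r", "neg_r"))
    if (length(spatial_vars)) {
      for (m in MOVEMENTS) {
        fs <- frame_pattern_correlations(patterns$spatial[, m], runs, roi)
        for (v in spatial_vars)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subject, movement = m, phase = phase, variant = v,
            cutoff = cdf_cutoff(fs$r, v, percentile),
            n_frames = length(fs$r), stringsAsFactors = FALSE)
      }
    }
    if ("spatiotemporal_r2" %in% variants) {
      win <- spatiotemporal_windows(runs, roi,
                                    window_s = diff(patterns$window),
                                    stride_frames = stride_frames)
      for (m in MOVEMENTS) {
        r <- as.vector(stats::cor(patterns$spatiotemporal[, m], win))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, movement = m, phase = phase,
          variant = "spatiotemporal_r2",
          cutoff = cdf_cutoff(r, "r2", percentile),
          n_frames = ncol(win), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
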