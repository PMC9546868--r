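#' Discard initial frames of a run
#'
#' Removes the first `n_drop` frames (TRs) of a scan — the frames acquired
#' before longitudinal magnetization reaches steady state — and restarts frame
#' times at zero.
#'
#' @param ts a [vertex_ts()].
#' @param n_drop number of leading frames to discard (default 4).
#' @return the shortened [vertex_ts()].
#' @seealso [realign_events()] to re-express task onsets relative to the new
#'   first frame.
#' @export
drop_initial_frames <- function(ts, n_drop = 4) {
  stopifnot(inherits(ts, "vertex_ts"))
  n_drop <- assert_count(n_drop, positive = FALSE)
  if (n_drop == 0L) return(ts)
  if (n_frames(ts) <= n_drop)
    stop(sprintf("run '%s' has %d frames, cannot drop %d",
                 ts$run_id, n_frames(ts), n_drop), call. = FALSE)
  ts$data <- ts$data[, -(seq_len(n_drop)), drop = FALSE]
  ts$frame_times <- (seq_len(ncol(ts$data)) - 1) * ts$tr_seconds
  ts
}

#' Re-express event onsets after frame dropping
#'
#' @param events an [event_table()].
#' @param n_drop frames dropped from the start of the run.
#' @param tr repetition time (s).
#' @return the shifted [event_table()] (onsets reduced by `n_drop * tr`).
#' @export
realign_events <- function(events, n_drop = 4, tr = 1) {
  validate_events(events)
  shifted <- events
  shifted$onset <- events$onset - n_drop * tr
  if (any(shifted$onset < 0))
    stop("frame dropping would place an event before the first retained frame",
         call. = FALSE)
  shifted
}

#' Global-signal regression
#'
#' Regresses the mean time course over `mask` (the "global signal", e.g. the
#' whole left hemisphere) out of every vertex's time course: each row of the
#' data is replaced by its least-squares residual on an intercept plus the
#' global signal. If the global signal has zero variance only the intercept is
#' removed, with a warning.
#'
#' @param ts a [vertex_ts()].
#' @param mask vertex indices defining the global signal (default: all).
#' @return the residualized [vertex_ts()].
#' @export
regress_global_signal <- function(ts, mask = seq_len(nrow(ts$data))) {
  stopifnot(inherits(ts, "vertex_ts"))
  if (length(mask) < 1L || any(mask < 1L) || any(mask > nrow(ts$data)))
    stop("'mask' must be a non-empty set of valid vertex indices", call. = FALSE)
  g <- colMeans(ts$data[mask, , drop = FALSE])
  if (stats::sd(g) < .Machine$double.eps^0.5) {
    warning("global signal is constant; removing intercept only", call. = FALSE)
    X <- matrix(1, length(g), 1L)
  } else {
    X <- cbind(1, g, deparse.level = 0)
  }
  # residuals of data' (frames x vertices) on X, vectorized across vertices
  ts$data <- t(stats::lm.fit(X, t(ts$data))$residuals)
  ts
}

#' Per-frame spatial z-scoring
#'
#' Converts every frame (TR) to a relative activation pattern: values are
#' centered and scaled so that, over the `roi` vertices, each frame has mean 0
#' and sample (ddof = 1) standard deviation 1. The same affine transform is
#' applied to all vertices so matrix dimensions are preserved. Frames whose
#' spatial variance over `roi` is zero cannot be standardized; they are
#' removed and recorded in `excluded_frames`, with a warning.
#'
#' @param ts a [vertex_ts()].
#' @param roi vertex indices defining the pattern space (default: all).
#' @return the standardized [vertex_ts()].
#' @export
zscore_frames <- function(ts, roi = seq_len(nrow(ts$data))) {
  stopifnot(inherits(ts, "vertex_ts"))
  if (length(roi) < 3L)
    stop("'roi' must contain at least 3 vertices", call. = FALSE)
  sub <- ts$data[roi, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- sqrt(colSums(sweep(sub, 2L, mu)^2) / (length(roi) - 1L))
  bad <- which(sdv < .Machine$double.eps^0.5)
  if (length(bad)) {
    warning(sprintf("run '%s': excluding %d zero-variance frame(s): %s",
                    ts$run_id, length(bad),
                    paste(bad - 1L, collapse = ", ")), call. = FALSE)
    ts$excluded_frames <- c(ts$excluded_frames, bad - 1L)
    ts$data <- ts$data[, -bad, drop = FALSE]
    ts$frame_times <- ts$frame_times[-bad]
    mu <- mu[-bad]; sdv <- sdv[-bad]
  }
  ts$data <- sweep(sweep(ts$data, 2L, mu), 2L, sdv, `/`)
  ts
}

#' Standard preprocessing chain for the main analyses
#'
#' Applies, in order: initial-frame exclusion, global-signal regression over
#' `mask`, and per-frame spatial z-scoring over `roi`. The order (GSR before
#' z-scoring) is part of the analysis contract.
#'
#' @param ts a [vertex_ts()].
#' @param roi vertex indices of the analysis ROI (z-scoring space).
#' @param mask vertex indices of the global-signal mask (default: all).
#' @param n_drop leading frames to discard.
#' @param gsr,zscore logical toggles.
#' @return the preprocessed [vertex_ts()].
#' @export
preprocess_run <- function(ts, roi = seq_len(nrow(ts$data)),
                           mask = seq_len(nrow(ts$data)),
                           n_drop = 4, gsr = TRUE, zscore = TRUE) {
  ts <- drop_initial_frames(ts, n_drop)
  if (gsr) ts <- regress_global_signal(ts, mask)
  if (zscore) ts <- zscore_frames(ts, roi)
  ts
}
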