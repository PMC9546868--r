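#' Construct a vertex x frame BOLD time-series object
#'
#' The basic per-run data container: a numeric matrix with vertices in rows and
#' frames (TRs) in columns, plus acquisition metadata. Frame `i` (0-based) is
#' acquired at time `i * tr_seconds`.
#'
#' @param data numeric matrix, vertices x frames.
#' @param tr_seconds repetition time in seconds.
#' @param run_id run identifier (string or integer).
#' @param scan_type one of `"task"`, `"rest_pre"`, `"rest_post"`.
#' @return an object of class `vertex_ts` with fields `data`, `tr_seconds`,
#'   `run_id`, `scan_type`, `frame_times` and an `excluded_frames` integer
#'   vector recording frames flagged during preprocessing.
#' @export
vertex_ts <- function(data, tr_seconds, run_id = "run-1",
                      scan_type = c("task", "rest_pre", "rest_post")) {
  scan_type <- match.arg(scan_type)
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 1L)
    stop("'data' must be a numeric matrix with at least one frame", call. = FALSE)
  if (anyNA(data)) stop("'data' contains missing values", call. = FALSE)
  assert_number(tr_seconds, positive = TRUE)
  structure(
    list(data = data,
         tr_seconds = as.numeric(tr_seconds),
         run_id = as.character(run_id),
         scan_type = scan_type,
         frame_times = (seq_len(ncol(data)) - 1) * as.numeric(tr_seconds),
         excluded_frames = integer(0)),
    class = "vertex_ts")
}

#' @export
print.vertex_ts <- function(x, ...) {
  cat(sprintf("<vertex_ts> %s (%s): %d vertices x %d frames, TR = %gs\n",
              x$run_id, x$scan_type, nrow(x$data), ncol(x$data), x$tr_seconds))
  if (length(x$excluded_frames))
    cat(sprintf("  %d frame(s) flagged for exclusion\n", length(x$excluded_frames)))
  invisible(x)
}

n_frames <- function(ts) ncol(ts$data)
n_vertices <- function(ts) nrow(ts$data)

#' Construct/validate an event table
#'
#' Block onsets, durations and movement labels for one task run, in the BIDS
#' `events.tsv` dialect (columns `onset`, `duration`, `trial_type`, seconds).
#'
#' @param onset numeric vector of block onsets (s).
#' @param duration numeric vector of block durations (s).
#' @param trial_type character vector of labels from [MOVEMENTS].
#' @return a `data.frame` of class `event_table`.
#' @export
event_table <- function(onset, duration, trial_type) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   stringsAsFactors = FALSE)
  validate_events(ev)
  class(ev) <- c("event_table", "data.frame")
  ev
}

validate_events <- function(ev) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(ev)))
  if (!all(ev$trial_type %in% MOVEMENTS))
    stop("trial_type labels must be in {", paste(MOVEMENTS, collapse = ", "), "}",
         call. = FALSE)
  if (is.unsorted(ev$onset, strictly = TRUE))
    stop("event onsets must be strictly increasing", call. = FALSE)
  ends <- ev$onset + ev$duration
  if (nrow(ev) > 1L && any(ev$onset[-1L] < ends[-nrow(ev)]))
    stop("event blocks overlap", call. = FALSE)
  invisible(ev)
}
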