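#' Write / read a vertex time series
#'
#' On-disk format: a plain tab-separated numeric matrix (vertices x frames, no
#' header or row names) plus a JSON sidecar `<path>.json` with `tr_seconds`,
#' `scan_type`, `run_id` and any excluded frames.
#'
#' @param ts a [vertex_ts()].
#' @param path destination `.tsv` file.
#' @return `path`, invisibly.
#' @export
write_ts <- function(ts, path) {
  stopifnot(inherits(ts, "vertex_ts"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(ts$data), path, sep = "\t",
                     col.names = FALSE)
  jsonlite::write_json(
    list(tr_seconds = ts$tr_seconds, scan_type = ts$scan_type,
         run_id = ts$run_id, excluded_frames = ts$excluded_frames),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ts
#' @param path source `.tsv` file (sidecar `<path>.json` must exist).
#' @export
read_ts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar JSON: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  data <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  ts <- vertex_ts(data, meta$tr_seconds, run_id = meta$run_id,
                  scan_type = meta$scan_type)
  ts$excluded_frames <- as.integer(meta$excluded_frames %||% integer(0))
  ts
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with header `onset  duration  trial_type` (seconds).
#'
#' @param events an [event_table()].
#' @param path destination `.tsv` file.
#' @return `path` (write) or the [event_table()] (read).
#' @export
write_events <- function(events, path) {
  validate_events(events)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(events)[, c("onset", "duration", "trial_type")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  event_table(ev$onset, ev$duration, ev$trial_type)
}

#' Write / read an ROI definition
#'
#' One vertex index per line (1-based) plus a JSON metadata sidecar
#' (`p_threshold`, `size`, `target_size`, `tolerance`, `achieved`). Externally
#' supplied ROIs (e.g. a control region) can use the same format; a missing
#' sidecar yields a plain ROI with `achieved = NA`.
#'
#' @param roi a [select_roi()] result.
#' @param path destination text file.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_definition"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(as.character(roi$vertex_ids), path)
  jsonlite::write_json(
    roi[c("p_threshold", "size", "target_size", "tolerance", "achieved")],
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  ids <- as.integer(readLines(path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(p_threshold = NA_real_, target_size = length(ids),
                    tolerance = NA_real_, achieved = NA)
  structure(list(vertex_ids = ids, p_threshold = meta$p_threshold,
                 size = length(ids), target_size = meta$target_size,
                 tolerance = meta$tolerance, achieved = meta$achieved),
            class = "roi_definition")
}

#' Write a simulated subject to the standard on-disk layout
#'
#' Layout under `dir/<subject_id>/`: `task_run-<r>_bold.tsv` (+ `.json`
#' sidecars), `task_run-<r>_events.tsv`, `rest_<phase>_run-<r>_bold.tsv`, and
#' `ground_truth.json` (patterns, active vertices, rest event log).
#'
#' @param bundle a [simulate_subject()] result.
#' @param dir output directory.
#' @return the subject directory, invisibly.
#' @export
write_subject <- function(bundle, dir) {
  stopifnot(inherits(bundle, "subject_bundle"))
  sdir <- file.path(dir, bundle$subject_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(bundle$task_runs)) {
    write_ts(bundle$task_runs[[r]], file.path(sdir, sprintf("task_run-%d_bold.tsv", r)))
    write_events(bundle$task_events[[r]],
                 file.path(sdir, sprintf("task_run-%d_events.tsv", r)))
  }
  for (phase in c("pre", "post")) {
    runs <- bundle[[paste0("rest_", phase)]]
    for (r in seq_along(runs))
      write_ts(runs[[r]], file.path(sdir, sprintf("rest_%s_run-%d_bold.tsv", phase, r)))
  }
  gt <- bundle$ground_truth
  jsonlite::write_json(
    list(patterns = as.data.frame(gt$patterns),
         active_vertices = gt$active_vertices,
         rest_event_log = gt$rest_event_log),
    file.path(sdir, "ground_truth.json"), digits = NA)
  invisible(sdir)
}

#' Read a subject written by [write_subject()]
#'
#' @param sdir subject directory.
#' @return a `subject_bundle` (without a `config`; `ground_truth` restored
#'   from JSON).
#' @export
read_subject <- function(sdir) {
  list_runs <- function(pat) {
    files <- sort(list.files(sdir, pattern = pat, full.names = TRUE))
    files <- files[!grepl("\\.json$", files)]
    lapply(files, read_ts)
  }
  task_runs <- list_runs("^task_run-[0-9]+_bold\\.tsv$")
  ev_files <- sort(list.files(sdir, pattern = "^task_run-[0-9]+_events\\.tsv$",
                              full.names = TRUE))
  gt_path <- file.path(sdir, "ground_truth.json")
  gt <- NULL
  if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt <- structure(list(patterns = as.matrix(g$patterns),
                         active_vertices = as.integer(g$active_vertices),
                         rest_event_log = as.data.frame(g$rest_event_log)),
                    class = "ground_truth")
  }
  structure(list(config = NULL, ground_truth = gt,
                 task_runs = task_runs,
                 task_events = lapply(ev_files, read_events),
                 rest_pre = list_runs("^rest_pre_run-[0-9]+_bold\\.tsv$"),
                 rest_post = list_runs("^rest_post_run-[0-9]+_bold\\.tsv$"),
                 rest_event_log = gt$rest_event_log,
                 subject_id = basename(sdir)),
            class = "subject_bundle")
}
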