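#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. In `"simulate"` mode a
#' synthetic cohort is generated under the output directory; in `"existing"`
#' mode subjects are read from `input_dir` (layout of [write_subject()]).
#'
#' @param out_dir output directory (created if needed).
#' @param mode `"simulate"` or `"existing"`.
#' @param input_dir directory of existing subjects (required for
#'   `"existing"`).
#' @param n_subjects cohort size in simulate mode.
#' @param sim named list of [sim_config()] overrides.
#' @param n_drop initial frames discarded from every run.
#' @param gsr apply global-signal regression.
#' @param roi_target,roi_tolerance adaptive ROI sizing parameters; the default
#'   target is the simulation's active-region size (2187 at full scale).
#' @param window training/pattern window (s after block onset).
#' @param test_window_s per-frame decoding test window (s).
#' @param percentile CDF cutoff level.
#' @param variants replay variants to compute.
#' @param stride_frames spatio-temporal window stride.
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, mode = c("simulate", "existing"),
                            input_dir = NULL, n_subjects = 15,
                            sim = list(), n_drop = 4, gsr = TRUE,
                            roi_target = NULL, roi_tolerance = 0.07,
                            window = c(10, 18), test_window_s = 28,
                            percentile = 0.90,
                            variants = c("r2", "r", "neg_r", "spatiotemporal_r2"),
                            stride_frames = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "existing" && (is.null(input_dir) || !dir.exists(input_dir)))
    stop("mode 'existing' requires an existing input_dir", call. = FALSE)
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must be in (0, 1)", call. = FALSE)
  sim_full <- do.call(sim_config, sim)
  structure(list(out_dir = out_dir, mode = mode, input_dir = input_dir,
                 n_subjects = assert_count(n_subjects), sim = sim,
                 n_drop = assert_count(n_drop, positive = FALSE), gsr = gsr,
                 roi_target = roi_target %||% sim_full$n_active_vertices,
                 roi_tolerance = roi_tolerance,
                 window = window, test_window_s = test_window_s,
                 percentile = percentile, variants = variants,
                 stride_frames = assert_count(stride_frames),
                 seed = assert_count(seed, positive = FALSE)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Analyse one subject end to end (in memory)
#'
#' Applies the full per-subject analysis to a [simulate_subject()] bundle:
#' frame dropping and event realignment; GLM ROI selection on the raw
#' (non-GSR, non-z-scored) task runs; global-signal regression and per-frame
#' z-scoring; mean-pattern construction; leave-one-run-out per-frame decoding;
#' and the replay cutoff table for both rest phases.
#'
#' @param bundle a `subject_bundle`.
#' @param tr repetition time (taken from the data).
#' @param n_drop,gsr,roi_target,roi_tolerance,window,test_window_s,percentile,variants,stride_frames
#'   see [pipeline_config()].
#' @param roi optional pre-defined ROI (vertex indices or [select_roi()]
#'   result); skips GLM selection.
#' @param decode run the decoding stage (can be skipped for speed).
#' @param hrf_delta,hrf_tau gamma HRF parameters for the ROI GLM.
#' @return list: `roi`, `glm` (NULL if `roi` supplied), `patterns`,
#'   `classification` (NULL if `decode = FALSE`), `cutoffs`, `events`
#'   (realigned), `task_pp`, `rest_pre_pp`, `rest_post_pp`.
#' @export
analyze_subject <- function(bundle, n_drop = 4, gsr = TRUE,
                            roi = NULL, roi_target = 2187, roi_tolerance = 0.07,
                            window = c(10, 18), test_window_s = 28,
                            percentile = 0.90,
                            variants = c("r2", "r", "neg_r", "spatiotemporal_r2"),
                            stride_frames = 1, decode = TRUE,
                            hrf_delta = 2.25, hrf_tau = 1.25) {
  tr <- bundle$task_runs[[1]]$tr_seconds
  raw <- lapply(bundle$task_runs, drop_initial_frames, n_drop = n_drop)
  events <- lapply(bundle$task_events, realign_events, n_drop = n_drop, tr = tr)
  glm <- NULL
  if (is.null(roi)) {
    hrf <- make_hrf(tr, hrf_delta, hrf_tau)
    designs <- lapply(seq_along(raw), function(r)
      build_design_matrix(events[[r]], hrf, ncol(raw[[r]]$data), tr))
    glm <- fit_glm(raw, designs)
    roi <- select_roi(glm, seq_len(nrow(raw[[1]]$data)),
                      target_size = roi_target, tolerance = roi_tolerance)
  }
  idx <- roi_indices(roi)
  pp <- function(ts) {
    ts <- if (gsr) regress_global_signal(ts) else ts
    zscore_frames(ts, idx)
  }
  task_pp <- lapply(raw, pp)
  rest_pp <- function(runs) lapply(runs, function(ts)
    pp(drop_initial_frames(ts, n_drop)))
  rest_pre_pp <- rest_pp(bundle$rest_pre)
  rest_post_pp <- rest_pp(bundle$rest_post)
  patterns <- compute_mean_patterns(
    extract_block_patterns(task_pp, events, idx, window))
  classification <- if (decode)
    crossval_timecourse(task_pp, events, idx, window, test_window_s) else NULL
  cutoffs <- replay_summary(rest_pre_pp, rest_post_pp, patterns, idx,
                            percentile = percentile, variants = variants,
                            stride_frames = stride_frames,
                            subject = bundle$subject_id)
  list(roi = roi, glm = glm, patterns = patterns,
       classification = classification, cutoffs = cutoffs,
       events = events, task_pp = task_pp,
       rest_pre_pp = rest_pre_pp, rest_post_pp = rest_post_pp)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> ROI -> preprocess/patterns -> decode -> replay ->
#' group stats over a cohort, writing stage outputs and provenance JSON under
#' `config$out_dir`. A stage is skipped when its provenance marker records the
#' same configuration hash (resumability); pass `force = TRUE` to recompute.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (dependencies are the caller's
#'   responsibility when subsetting).
#' @param force recompute even when provenance matches.
#' @return list: `out_dir`, `hash`, `skipped` (named logical), `cutoffs`,
#'   `accuracy`, `stats` (data.frames; NULL for stages not run).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "analyze", "stats"),
                         force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(file.path(out, "provenance"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "derivatives"), recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  skipped <- c(simulate = FALSE, analyze = FALSE, stats = FALSE)
  marker <- function(stage) file.path(out, "provenance", paste0(stage, ".json"))
  stage_done <- function(stage) {
    f <- marker(stage)
    !force && file.exists(f) &&
      identical(jsonlite::read_json(f)$config_hash, hash)
  }
  mark <- function(stage, extra = list()) {
    jsonlite::write_json(
      c(list(stage = stage, config_hash = hash, seed = config$seed,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             package_version = as.character(utils::packageVersion("restreplay"))),
        extra),
      marker(stage), auto_unbox = TRUE, digits = NA)
  }
  subjects_dir <- if (config$mode == "simulate") file.path(out, "subjects")
                  else config$input_dir

  subject_ids <- sprintf("sub-%02d", seq_len(config$n_subjects))
  if ("simulate" %in% stages && config$mode == "simulate") {
    if (stage_done("simulate")) {
      skipped["simulate"] <- TRUE
    } else {
      for (s in seq_len(config$n_subjects)) {
        cfg_s <- do.call(sim_config,
                         c(config$sim,
                           list(seed = derive_seed(config$seed, 10L, s))))
        simulate_subject(cfg_s, out_dir = subjects_dir,
                         subject_id = subject_ids[s])
      }
      mark("simulate", list(n_subjects = config$n_subjects))
    }
  }
  if (config$mode == "existing")
    subject_ids <- basename(sort(list.dirs(subjects_dir, recursive = FALSE)))

  cutoffs <- accuracy <- stats_tab <- NULL
  if ("analyze" %in% stages) {
    cut_path <- file.path(out, "derivatives", "cutoffs.tsv")
    acc_path <- file.path(out, "derivatives", "accuracy.tsv")
    if (stage_done("analyze")) {
      skipped["analyze"] <- TRUE
      cutoffs <- as.data.frame(data.table::fread(cut_path))
      accuracy <- as.data.frame(data.table::fread(acc_path))
    } else {
      all_cut <- list(); all_acc <- list()
      for (sid in subject_ids) {
        bundle <- read_subject(file.path(subjects_dir, sid))
        res <- analyze_subject(
          bundle, n_drop = config$n_drop, gsr = config$gsr,
          roi_target = config$roi_target, roi_tolerance = config$roi_tolerance,
          window = config$window, test_window_s = config$test_window_s,
          percentile = config$percentile, variants = config$variants,
          stride_frames = config$stride_frames)
        sdir <- file.path(out, "derivatives", sid)
        write_roi(res$roi, file.path(sdir, "roi.txt"))
        acc <- data.frame(subject = sid,
                          frame_index = as.integer(names(res$classification$per_tr_accuracy)),
                          accuracy = res$classification$per_tr_accuracy,
                          n = res$classification$per_tr_n)
        data.table::fwrite(acc, file.path(sdir, "accuracy.tsv"), sep = "\t")
        data.table::fwrite(as.data.frame(res$classification$confusion),
                           file.path(sdir, "confusion.tsv"), sep = "\t")
        data.table::fwrite(res$cutoffs, file.path(sdir, "cutoffs.tsv"), sep = "\t")
        all_cut[[sid]] <- res$cutoffs
        all_acc[[sid]] <- acc
      }
      cutoffs <- do.call(rbind, all_cut)
      accuracy <- do.call(rbind, all_acc)
      data.table::fwrite(cutoffs, cut_path, sep = "\t")
      data.table::fwrite(accuracy, acc_path, sep = "\t")
      mark("analyze", list(n_subjects = length(subject_ids)))
    }
  }
  if ("stats" %in% stages) {
    stats_path <- file.path(out, "derivatives", "stats.tsv")
    if (stage_done("stats")) {
      skipped["stats"] <- TRUE
      stats_tab <- as.data.frame(data.table::fread(stats_path))
    } else {
      if (is.null(cutoffs))
        cutoffs <- as.data.frame(data.table::fread(
          file.path(out, "derivatives", "cutoffs.tsv")))
      stats_tab <- analyze_experiment(cutoffs)
      data.table::fwrite(stats_tab, stats_path, sep = "\t")
      if (!is.null(accuracy)) {
        acc_wide <- stats::reshape(
          accuracy[, c("subject", "frame_index", "accuracy")],
          direction = "wide", idvar = "subject", timevar = "frame_index")
        gi <- accuracy_group_inference(as.matrix(acc_wide[, -1, drop = FALSE]))
        data.table::fwrite(gi, file.path(out, "derivatives", "accuracy_group.tsv"),
                           sep = "\t")
      }
      mark("stats")
    }
  }
  list(out_dir = out, hash = hash, skipped = skipped,
       cutoffs = cutoffs, accuracy = accuracy, stats = stats_tab)
}

#' Validate an input directory
#'
#' Report-only conformance check of a subjects directory in the
#' [write_subject()] layout: parseable matrices and event tables, sidecar
#' metadata present, consistent vertex counts across a subject's runs,
#' movement-label vocabulary, strictly increasing non-overlapping onsets.
#'
#' @param dir directory containing `sub-*` subject subdirectories.
#' @return data.frame (`subject`, `file`, `issue`); zero rows when pristine.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(subject, file, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      subject = subject, file = file, issue = issue, stringsAsFactors = FALSE)
  subs <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(subs))
    return(data.frame(subject = character(0), file = character(0),
                      issue = character(0)))
  for (sdir in subs) {
    sid <- basename(sdir)
    bold <- sort(list.files(sdir, pattern = "_bold\\.tsv$", full.names = TRUE))
    nvert <- NA_integer_
    for (f in bold) {
      if (!file.exists(paste0(f, ".json"))) {
        note(sid, basename(f), "missing sidecar JSON")
        next
      }
      ts <- tryCatch(read_ts(f), error = function(e) e)
      if (inherits(ts, "error")) {
        note(sid, basename(f), paste("unreadable:", conditionMessage(ts)))
        next
      }
      if (is.na(nvert)) nvert <- nrow(ts$data)
      else if (nrow(ts$data) != nvert)
        note(sid, basename(f),
             sprintf("vertex count %d differs from %d", nrow(ts$data), nvert))
    }
    for (f in sort(list.files(sdir, pattern = "_events\\.tsv$", full.names = TRUE))) {
      raw <- tryCatch(as.data.frame(data.table::fread(f, sep = "\t")),
                      error = function(e) e)
      if (inherits(raw, "error")) {
        note(sid, basename(f), "unparseable events table")
        next
      }
      if (!all(c("onset", "duration", "trial_type") %in% names(raw))) {
        note(sid, basename(f), "missing onset/duration/trial_type columns")
        next
      }
      bad <- setdiff(unique(raw$trial_type), MOVEMENTS)
      for (b in bad)
        note(sid, basename(f), sprintf("unknown trial_type '%s'", b))
      if (is.unsorted(raw$onset, strictly = TRUE))
        note(sid, basename(f), "onsets not strictly increasing")
      else if (nrow(raw) > 1L &&
               any(raw$onset[-1L] < (raw$onset + raw$duration)[-nrow(raw)]))
        note(sid, basename(f), "overlapping blocks")
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(subject = character(0), file = character(0),
                  issue = character(0))
}
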