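# shared fixtures: scaled-down simulation worlds used across test files.
# Vertex counts and rest durations are reduced from the full-scale defaults so
# the suite runs in minutes; properties asserted are scale-free.

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_vertices = 120, n_active_vertices = 80,
                   rest_run_duration_s = 120,
                   n_rest_runs_pre = 2, n_rest_runs_post = 2, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# a tiny deterministic vertex_ts from an explicit matrix
ts_from <- function(m, tr = 1, scan_type = "task", run_id = "toy") {
  vertex_ts(as.matrix(m), tr_seconds = tr, run_id = run_id,
            scan_type = scan_type)
}

# one analysed small subject, cached per test session
cached_subject_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- simulate_subject(small_cfg(seed = 11L))
      cache <<- list(bundle = b,
                     res = analyze_subject(b, roi_target = 80,
                                           roi_tolerance = 0.07))
    }
    cache
  }
})
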