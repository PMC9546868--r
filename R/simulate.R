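#' Simulation configuration
#'
#' Assembles and validates the full parameter set for the synthetic
#' surface-sampled BOLD generator. Defaults reproduce the acquisition the
#' downstream analysis assumes: five task runs of twelve 10-s movement blocks
#' (three per movement) separated by 20-24 s rest gaps, three 5-minute rest
#' runs before and three after the task, TR of 1 s, and a 2187-vertex
#' responsive region embedded in a larger hemisphere mask. The four
#' ground-truth movement patterns are built so that Grip/Extend/Pinch are
#' mutually more similar (r = `ecological_similarity`) than any of them is to
#' Shake (r = `control_similarity`).
#'
#' @param n_vertices total vertices in the hemisphere mask.
#' @param n_active_vertices vertices in the ground-truth responsive region.
#' @param tr_seconds repetition time (s); must divide block and rest-run
#'   durations evenly.
#' @param n_task_runs,blocks_per_movement_per_run,block_duration_s task design.
#' @param rest_gap_range_s integer interval (inclusive) of rest-gap durations
#'   between consecutive task blocks, seconds.
#' @param n_rest_runs_pre,n_rest_runs_post,rest_run_duration_s rest design.
#' @param hrf_delta,hrf_tau gamma HRF onset delay and dispersion (s).
#' @param pattern_amplitude peak amplitude of a movement block's pattern
#'   response, in units of `noise_sd`.
#' @param common_activation amplitude of the movement-independent evoked
#'   response shared by all active vertices (in units of the pattern's
#'   standard deviation). This is what makes the region show up as a positive
#'   task-vs-baseline GLM contrast; the movement-specific pattern rides on top
#'   of it. Setting it to 0 leaves only the zero-mean pattern component.
#' @param noise_sd standard deviation of i.i.d. Gaussian measurement noise.
#' @param global_noise_sd standard deviation of a frame-wise fluctuation
#'   shared by every vertex — the global physiological nuisance signal that
#'   global-signal regression is designed to remove. Without it the simulated
#'   global mean would be essentially noise-free and GSR would remove shared
#'   signals of interest far more aggressively than it can in real data.
#' @param baseline_level constant baseline BOLD intensity added everywhere so
#'   that percent-signal-change is well defined.
#' @param ecological_similarity,control_similarity target Pearson correlations
#'   among ground-truth patterns (within {Grip,Extend,Pinch}, and of each with
#'   Shake).
#' @param rest_event_rate_per_min named per-movement rates (events/minute) of
#'   the Poisson replay-event process embedded in PRE-task rest runs.
#' @param rest_event_rate_post_per_min same for POST-task rest runs; defaults
#'   to zero everywhere (the post-task default world has no replay, emulating
#'   pattern-specific adaptation after task performance).
#' @param rest_event_amplitude peak amplitude of an embedded rest transient;
#'   defaults to `pattern_amplitude`.
#' @param seed master integer seed; all outputs are pure functions of
#'   (config, seed).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_vertices = 5000,
                       n_active_vertices = 2187,
                       tr_seconds = 1,
                       n_task_runs = 5,
                       blocks_per_movement_per_run = 3,
                       block_duration_s = 10,
                       rest_gap_range_s = c(20, 24),
                       n_rest_runs_pre = 3,
                       n_rest_runs_post = 3,
                       rest_run_duration_s = 300,
                       hrf_delta = 2.25,
                       hrf_tau = 1.25,
                       pattern_amplitude = 0.5,
                       common_activation = 2,
                       noise_sd = 1,
                       global_noise_sd = 0.5,
                       baseline_level = 100,
                       ecological_similarity = 0.5,
                       control_similarity = 0.1,
                       rest_event_rate_per_min = c(Grip = 4, Extend = 3,
                                                   Pinch = 3, Shake = 0.5),
                       rest_event_rate_post_per_min = c(Grip = 0, Extend = 0,
                                                        Pinch = 0, Shake = 0),
                       rest_event_amplitude = NULL,
                       seed = 1L) {
  cfg <- list(
    n_vertices = assert_count(n_vertices),
    n_active_vertices = assert_count(n_active_vertices),
    tr_seconds = assert_number(tr_seconds, positive = TRUE),
    n_task_runs = assert_count(n_task_runs),
    blocks_per_movement_per_run = assert_count(blocks_per_movement_per_run),
    block_duration_s = assert_number(block_duration_s, positive = TRUE),
    rest_gap_range_s = rest_gap_range_s,
    n_rest_runs_pre = assert_count(n_rest_runs_pre, positive = FALSE),
    n_rest_runs_post = assert_count(n_rest_runs_post, positive = FALSE),
    rest_run_duration_s = assert_number(rest_run_duration_s, positive = TRUE),
    hrf_delta = assert_number(hrf_delta, positive = TRUE),
    hrf_tau = assert_number(hrf_tau, positive = TRUE),
    pattern_amplitude = assert_number(pattern_amplitude),
    common_activation = assert_number(common_activation),
    noise_sd = assert_number(noise_sd),
    global_noise_sd = assert_number(global_noise_sd),
    baseline_level = assert_number(baseline_level),
    ecological_similarity = assert_number(ecological_similarity),
    control_similarity = assert_number(control_similarity),
    rest_event_rate_per_min = fill_rates(rest_event_rate_per_min),
    rest_event_rate_post_per_min = fill_rates(rest_event_rate_post_per_min),
    rest_event_amplitude = assert_number(rest_event_amplitude %||% pattern_amplitude),
    seed = assert_count(seed, positive = FALSE)
  )
  if (cfg$n_active_vertices > cfg$n_vertices)
    stop("n_active_vertices cannot exceed n_vertices", call. = FALSE)
  if (cfg$n_active_vertices < 5L)
    stop("n_active_vertices must be at least 5", call. = FALSE)
  if (length(cfg$rest_gap_range_s) != 2L ||
      any(cfg$rest_gap_range_s != round(cfg$rest_gap_range_s)) ||
      cfg$rest_gap_range_s[1] > cfg$rest_gap_range_s[2] ||
      cfg$rest_gap_range_s[1] <= 0)
    stop("rest_gap_range_s must be an increasing pair of positive integers",
         call. = FALSE)
  for (d in c(cfg$block_duration_s, cfg$rest_run_duration_s))
    if (abs(d / cfg$tr_seconds - round(d / cfg$tr_seconds)) > 1e-9)
      stop("tr_seconds must divide block and rest-run durations evenly",
           call. = FALSE)
  for (r in c(cfg$ecological_similarity, cfg$control_similarity))
    if (r <= -1 || r >= 1)
      stop("similarity targets must lie in (-1, 1)", call. = FALSE)
  if (any(cfg$rest_event_rate_per_min < 0) ||
      any(cfg$rest_event_rate_post_per_min < 0))
    stop("rest event rates must be non-negative", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$global_noise_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

fill_rates <- function(r) {
  if (is.null(names(r)) && length(r) == 1L) r <- rep(r, 4L)
  if (is.null(names(r)) && length(r) == 4L) names(r) <- MOVEMENTS
  if (!all(MOVEMENTS %in% names(r)))
    stop("rest event rates must be named for all of: ",
         paste(MOVEMENTS, collapse = ", "), call. = FALSE)
  vapply(MOVEMENTS, function(m) assert_number(r[[m]]), numeric(1))
}

#' Gamma hemodynamic response kernel
#'
#' Samples the FS-FAST-style gamma impulse response
#' \deqn{h(t) = ((t-\Delta)/\tau)^2 \exp(-(t-\Delta)/\tau)} for `t >= delta`
#' (0 before), at multiples of the TR over a support of `delta + 10 * tau`
#' seconds, scaled to unit peak so that pattern amplitudes are interpretable
#' as peak responses. The analytic maximum of the kernel lies at
#' `t = delta + 2 * tau`.
#'
#' @param tr sampling interval (s).
#' @param delta onset delay Delta (s), default 2.25.
#' @param tau dispersion tau (s), default 1.25.
#' @return numeric vector `h`, `h[i]` sampled at `t = (i-1) * tr`.
#' @export
make_hrf <- function(tr, delta = 2.25, tau = 1.25) {
  assert_number(tr, positive = TRUE)
  assert_number(delta, positive = TRUE)
  assert_number(tau, positive = TRUE)
  t <- seq(0, delta + 10 * tau, by = tr)
  s <- (t - delta) / tau
  h <- ifelse(t >= delta, s^2 * exp(-s), 0)
  peak <- 4 * exp(-2) # value of s^2 exp(-s) at its maximum s = 2
  h / peak
}

# convolve a frame-sampled stimulus vector with the HRF kernel, truncated to
# the run length (linear-systems BOLD assumption: overlapping responses sum)
convolve_hrf <- function(stim, hrf) {
  n <- length(stim)
  full <- stats::convolve(stim, rev(hrf), type = "open")
  full[seq_len(n)]
}

#' Generate one task run's block design
#'
#' Each movement occurs `blocks_per_movement_per_run` times in a seeded random
#' order; consecutive blocks are separated by an integer rest gap drawn
#' uniformly from `rest_gap_range_s`. The run starts with a leading rest gap
#' (same distribution) and ends with a 20-s tail so the last response is
#' sampled. Total run duration in seconds is attached as attribute
#' `run_duration_s` (rounded up to a whole number of TRs).
#'
#' @param config a [sim_config()].
#' @param run_seed integer seed for this run's order and gaps.
#' @return an [event_table()].
#' @export
make_design <- function(config, run_seed) {
  stopifnot(inherits(config, "sim_config"))
  gaps_from <- seq(config$rest_gap_range_s[1], config$rest_gap_range_s[2])
  n_blocks <- 4L * config$blocks_per_movement_per_run
  with_seed(run_seed, {
    order <- sample(rep(MOVEMENTS, config$blocks_per_movement_per_run))
    gaps <- sample(gaps_from, n_blocks, replace = TRUE)
  })
  onsets <- cumsum(gaps + c(0, rep(config$block_duration_s, n_blocks - 1L)))
  ev <- event_table(onset = onsets,
                    duration = rep(config$block_duration_s, n_blocks),
                    trial_type = order)
  dur <- onsets[n_blocks] + config$block_duration_s + 20
  attr(ev, "run_duration_s") <-
    ceiling(dur / config$tr_seconds) * config$tr_seconds
  ev
}

#' Ground-truth movement patterns with controlled similarity geometry
#'
#' Builds four unit-variance spatial patterns over the active region whose
#' pairwise Pearson correlations equal the configured targets exactly: seeded
#' Gaussian vectors are column-centered and orthonormalized, then mixed with a
#' symmetric square root of the target correlation matrix. An infeasible
#' (non positive semi-definite) target matrix is an error.
#'
#' @param config a [sim_config()].
#' @return a list of class `ground_truth` with `patterns`
#'   (`n_active_vertices` x 4 matrix, columns named by movement),
#'   `active_vertices` (indices into the hemisphere mask) and an initially
#'   empty `rest_event_log`.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- target_correlation_matrix(config$ecological_similarity,
                                 config$control_similarity)
  ei <- eigen(R, symmetric = TRUE)
  if (min(ei$values) < -1e-8)
    stop("infeasible similarity targets: correlation matrix is not ",
         "positive semi-definite", call. = FALSE)
  sqrtR <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0))) %*% t(ei$vectors)
  n <- config$n_active_vertices
  with_seed(derive_seed(config$seed, 0L), {
    Z <- matrix(stats::rnorm(n * 4L), n, 4L)
    active <- sort(sample.int(config$n_vertices, n))
  })
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z)) # orthonormal, columns centered (combinations of centered Z)
  X <- Q %*% sqrtR * sqrt(n - 1) # unit sample variance, exact correlations R
  colnames(X) <- MOVEMENTS
  structure(list(patterns = X, active_vertices = active,
                 rest_event_log = data.frame(run_id = character(0),
                                             onset_frame = integer(0),
                                             movement = character(0))),
            class = "ground_truth")
}

target_correlation_matrix <- function(eco, ctrl) {
  R <- matrix(ctrl, 4, 4, dimnames = list(MOVEMENTS, MOVEMENTS))
  R[ECOLOGICAL, ECOLOGICAL] <- eco
  diag(R) <- 1
  R
}

#' Simulate one task run
#'
#' Forward model: each block contributes
#' `pattern_amplitude * (boxcar convolved with the HRF) *
#' (common_activation + pattern)` on the active vertices; i.i.d. Gaussian
#' noise (sd `noise_sd`) plus the constant `baseline_level` everywhere;
#' inactive vertices carry baseline + noise only. Overlapping response tails
#' from adjacent blocks sum linearly.
#'
#' @param config a [sim_config()].
#' @param ground_truth a [make_ground_truth()] result.
#' @param events an [event_table()] from [make_design()].
#' @param run_seed integer noise seed.
#' @param run_id run identifier.
#' @return a [vertex_ts()] of `n_vertices` x (run duration / TR).
#' @export
simulate_task_run <- function(config, ground_truth, events, run_seed,
                              run_id = "task_run-1") {
  stopifnot(inherits(config, "sim_config"), inherits(ground_truth, "ground_truth"))
  dur <- attr(events, "run_duration_s") %||%
    (max(events$onset + events$duration) + 20)
  nf <- as.integer(round(dur / config$tr_seconds))
  if (max(events$onset + events$duration) > dur)
    stop("events exceed run duration", call. = FALSE)
  ft <- (seq_len(nf) - 1) * config$tr_seconds
  hrf <- make_hrf(config$tr_seconds, config$hrf_delta, config$hrf_tau)
  # per-movement HRF-convolved regressors
  regs <- vapply(MOVEMENTS, function(m) {
    stim <- rep(0, nf)
    for (i in which(events$trial_type == m))
      stim[ft >= events$onset[i] & ft < events$onset[i] + events$duration[i]] <- 1
    convolve_hrf(stim, hrf)
  }, numeric(nf))
  with_seed(run_seed, {
    data <- matrix(stats::rnorm(config$n_vertices * nf, sd = config$noise_sd),
                   config$n_vertices, nf)
    gnoise <- stats::rnorm(nf, sd = config$global_noise_sd)
  })
  data <- sweep(data, 2L, gnoise, `+`) + config$baseline_level
  act <- ground_truth$active_vertices
  data[act, ] <- data[act, ] + config$pattern_amplitude *
    ((ground_truth$patterns + config$common_activation) %*% t(regs))
  vertex_ts(data, config$tr_seconds, run_id = run_id, scan_type = "task")
}

#' Simulate one resting-state run with embedded replay events
#'
#' For each movement, event onset frames are drawn from a Poisson process at
#' the phase's configured rate; each event adds
#' `rest_event_amplitude * HRF-shaped transient * (common_activation +
#' pattern)` on the active vertices (transients from different events sum
#' linearly). Gaussian noise and baseline as in task runs. All embedded events
#' are returned in the log.
#'
#' @param config a [sim_config()].
#' @param ground_truth a [make_ground_truth()] result.
#' @param phase `"pre"` or `"post"`; selects the rate vector.
#' @param run_seed integer seed.
#' @param run_id run identifier.
#' @return list with elements `ts` (a [vertex_ts()]) and `events`
#'   (data.frame `run_id`, `onset_frame` 0-based, `movement`).
#' @export
simulate_rest_run <- function(config, ground_truth, phase = c("pre", "post"),
                              run_seed, run_id = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "sim_config"), inherits(ground_truth, "ground_truth"))
  rates <- if (phase == "pre") config$rest_event_rate_per_min
           else config$rest_event_rate_post_per_min
  run_id <- run_id %||% sprintf("rest_%s_run-1", phase)
  nf <- as.integer(round(config$rest_run_duration_s / config$tr_seconds))
  hrf <- make_hrf(config$tr_seconds, config$hrf_delta, config$hrf_tau)
  dur_min <- config$rest_run_duration_s / 60
  log <- list()
  with_seed(run_seed, {
    stim <- matrix(0, nf, 4L, dimnames = list(NULL, MOVEMENTS))
    for (m in MOVEMENTS) {
      k <- stats::rpois(1L, rates[[m]] * dur_min)
      if (k > 0) {
        onsets <- sort(sample.int(nf, k, replace = TRUE)) - 1L # 0-based frames
        for (o in onsets) stim[o + 1L, m] <- stim[o + 1L, m] + 1
        log[[m]] <- data.frame(run_id = run_id, onset_frame = onsets,
                               movement = m, stringsAsFactors = FALSE)
      }
    }
    noise <- matrix(stats::rnorm(config$n_vertices * nf, sd = config$noise_sd),
                    config$n_vertices, nf)
    gnoise <- stats::rnorm(nf, sd = config$global_noise_sd)
  })
  regs <- apply(stim, 2L, convolve_hrf, hrf = hrf)
  data <- sweep(noise, 2L, gnoise, `+`) + config$baseline_level
  act <- ground_truth$active_vertices
  data[act, ] <- data[act, ] + config$rest_event_amplitude *
    ((ground_truth$patterns + config$common_activation) %*% t(regs))
  ts <- vertex_ts(data, config$tr_seconds, run_id = run_id,
                  scan_type = paste0("rest_", phase))
  events <- if (length(log)) do.call(rbind, unname(log))
            else data.frame(run_id = character(0), onset_frame = integer(0),
                            movement = character(0))
  list(ts = ts, events = events)
}

#' Simulate a full subject
#'
#' Generates the ground truth, all task runs with their designs, and the pre-
#' and post-task rest runs, all in a consistent vertex space and derived
#' deterministically from `config$seed`. Optionally writes the standard
#' on-disk layout (see [write_subject()]).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given the subject is written there.
#' @param subject_id identifier used in file names.
#' @return a list of class `subject_bundle`: `config`, `ground_truth`,
#'   `task_runs` (list of [vertex_ts()]), `task_events` (list of
#'   [event_table()]), `rest_pre`, `rest_post` (lists of [vertex_ts()]),
#'   `rest_event_log`.
#' @export
simulate_subject <- function(config, out_dir = NULL, subject_id = "sub-01") {
  stopifnot(inherits(config, "sim_config"))
  gt <- make_ground_truth(config)
  task_events <- list(); task_runs <- list()
  for (r in seq_len(config$n_task_runs)) {
    ev <- make_design(config, derive_seed(config$seed, 1L, r))
    task_events[[r]] <- ev
    task_runs[[r]] <- simulate_task_run(config, gt, ev,
                                        derive_seed(config$seed, 2L, r),
                                        run_id = sprintf("task_run-%d", r))
  }
  sim_rest <- function(phase, idx, stream) {
    lapply(seq_len(idx), function(r)
      simulate_rest_run(config, gt, phase, derive_seed(config$seed, stream, r),
                        run_id = sprintf("rest_%s_run-%d", phase, r)))
  }
  pre <- sim_rest("pre", config$n_rest_runs_pre, 3L)
  post <- sim_rest("post", config$n_rest_runs_post, 4L)
  logs <- c(lapply(pre, `[[`, "events"), lapply(post, `[[`, "events"))
  gt$rest_event_log <- do.call(rbind, logs)
  bundle <- structure(list(config = config, ground_truth = gt,
                           task_runs = task_runs, task_events = task_events,
                           rest_pre = lapply(pre, `[[`, "ts"),
                           rest_post = lapply(post, `[[`, "ts"),
                           rest_event_log = gt$rest_event_log,
                           subject_id = subject_id),
                      class = "subject_bundle")
  if (!is.null(out_dir)) write_subject(bundle, out_dir)
  bundle
}

#' Simulate a subject with a graded activation map
#'
#' Produces task runs in which a subset of vertices carries a combined-task
#' response whose amplitude increases linearly across the signal vertices
#' (from `max_amplitude / n_signal` up to `max_amplitude`), yielding a graded
#' GLM p-map. Used to exercise adaptive-threshold ROI sizing, where the
#' selection procedure must find a p-level carving out a target vertex count
#' from a continuum of effect sizes.
#'
#' @param n_vertices total vertices in the candidate mask.
#' @param n_signal vertices carrying graded signal.
#' @param max_amplitude amplitude of the strongest vertex (noise-sd units).
#' @param config a [sim_config()] supplying the design/timing/noise parameters.
#' @param seed integer seed.
#' @return list with `runs` (list of [vertex_ts()]), `events` (list of
#'   [event_table()]), `signal_vertices`, `amplitudes`.
#' @export
simulate_graded_activation <- function(n_vertices = 5000, n_signal = 3000,
                                       max_amplitude = 0.2,
                                       config = sim_config(), seed = 42L) {
  assert_count(n_vertices); assert_count(n_signal)
  stopifnot(n_signal <= n_vertices)
  hrf <- make_hrf(config$tr_seconds, config$hrf_delta, config$hrf_tau)
  sig <- with_seed(derive_seed(seed, 0L),
                   sort(sample.int(n_vertices, n_signal)))
  amp <- numeric(n_vertices)
  amp[sig] <- max_amplitude * seq_len(n_signal) / n_signal
  runs <- list(); events <- list()
  for (r in seq_len(config$n_task_runs)) {
    ev <- make_design(config, derive_seed(seed, 1L, r))
    dur <- attr(ev, "run_duration_s")
    nf <- as.integer(round(dur / config$tr_seconds))
    ft <- (seq_len(nf) - 1) * config$tr_seconds
    stim <- rep(0, nf)
    for (i in seq_len(nrow(ev)))
      stim[ft >= ev$onset[i] & ft < ev$onset[i] + ev$duration[i]] <- 1
    reg <- convolve_hrf(stim, hrf)
    with_seed(derive_seed(seed, 2L, r), {
      data <- matrix(stats::rnorm(n_vertices * nf, sd = config$noise_sd),
                     n_vertices, nf)
      gnoise <- stats::rnorm(nf, sd = config$global_noise_sd)
    })
    data <- sweep(data, 2L, gnoise, `+`) + config$baseline_level + outer(amp, reg)
    events[[r]] <- ev
    runs[[r]] <- vertex_ts(data, config$tr_seconds,
                           run_id = sprintf("task_run-%d", r), scan_type = "task")
  }
  list(runs = runs, events = events, signal_vertices = sig,
       amplitudes = amp[sig])
}
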