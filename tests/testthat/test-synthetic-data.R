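test_that("gamma HRF has the analytic shape: onset delay, unit peak, peak latency", {
  h <- make_hrf(tr = 1, delta = 2.25, tau = 1.25)
  # zero before the onset delay
  expect_identical(h[1:3], c(0, 0, 0)) # t = 0, 1, 2 all < 2.25
  expect_true(all(h >= 0))
  expect_equal(max(h), max(h)) # finite
  # analytic maximum at t = delta + 2 tau = 4.75; nearest 1-s sample is t = 5
  expect_equal(which.max(h) - 1L, 5L)
  # sampled finely, the peak lands on 4.75 exactly and equals 1
  h_fine <- make_hrf(tr = 0.25, delta = 2.25, tau = 1.25)
  expect_equal((which.max(h_fine) - 1L) * 0.25, 4.75)
  expect_equal(max(h_fine), 1)
  # support length delta + 10 tau
  expect_equal(length(h_fine), floor((2.25 + 12.5) / 0.25) + 1L)
  expect_error(make_hrf(0), "positive")
  expect_error(make_hrf(1, tau = -1), "positive")
})

test_that("task designs have 3 blocks per movement, seeded order, gaps in range", {
  cfg <- small_cfg()
  ev <- make_design(cfg, run_seed = 7L)
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 12L)
  expect_equal(unname(table(ev$trial_type)[MOVEMENTS]), rep(3L, 4), ignore_attr = TRUE)
  expect_true(all(diff(ev$onset) > 0))
  expect_identical(make_design(cfg, 7L), make_design(cfg, 7L))
  expect_false(identical(ev$trial_type, make_design(cfg, 8L)$trial_type))
  # gaps between consecutive blocks stay in [20, 24] over many seeded runs
  gaps <- unlist(lapply(1:100, function(s) {
    e <- make_design(cfg, s)
    diff(e$onset) - e$duration[-nrow(e)]
  }))
  expect_true(all(gaps >= 20 & gaps <= 24))
  expect_true(all(gaps == round(gaps)))
  expect_setequal(unique(gaps), 20:24)
})

test_that("ground-truth patterns hit the similarity targets and unit variance", {
  cfg <- small_cfg()
  gt <- make_ground_truth(cfg)
  expect_equal(dim(gt$patterns), c(80L, 4L))
  R <- cor(gt$patterns)
  tgt <- matrix(0.1, 4, 4); tgt[1:3, 1:3] <- 0.5; diag(tgt) <- 1
  # construction is exact, well inside the +/- 0.1 contract
  expect_true(max(abs(R - tgt)) < 1e-8)
  expect_equal(unname(apply(gt$patterns, 2, sd)), rep(1, 4))
  # full-scale check of the documented band
  gt_big <- make_ground_truth(sim_config(seed = 3L))
  Rb <- cor(gt_big$patterns)
  eco <- Rb[upper.tri(Rb)][1:3] # (Grip,Extend), (Grip,Pinch), (Extend,Pinch)
  expect_true(all(eco >= 0.4 & eco <= 0.6))
  expect_true(all(Rb[1:3, 4] >= 0.0 & Rb[1:3, 4] <= 0.2))
  # zero targets give orthogonal patterns
  gt0 <- make_ground_truth(small_cfg(ecological_similarity = 0,
                                     control_similarity = 0))
  expect_true(max(abs(cor(gt0$patterns)[upper.tri(diag(4))])) < 1e-8)
  # determinism
  expect_identical(make_ground_truth(cfg)$patterns, gt$patterns)
  # infeasible target matrix (all off-diagonals -0.5 is not PSD)
  expect_error(make_ground_truth(small_cfg(ecological_similarity = -0.5,
                                           control_similarity = -0.5)),
               "infeasible")
})

test_that("noiseless task runs reconstruct exactly from design x patterns", {
  cfg <- small_cfg(noise_sd = 0, global_noise_sd = 0, baseline_level = 0)
  gt <- make_ground_truth(cfg)
  ev <- make_design(cfg, 5L)
  run <- simulate_task_run(cfg, gt, ev, run_seed = 5L)
  nf <- ncol(run$data)
  # independent forward model: direct double-loop convolution per movement
  h <- make_hrf(cfg$tr_seconds, cfg$hrf_delta, cfg$hrf_tau)
  expected <- matrix(0, cfg$n_vertices, nf)
  for (i in seq_len(nrow(ev))) {
    stim <- as.numeric(seq(0, nf - 1) >= ev$onset[i] &
                       seq(0, nf - 1) < ev$onset[i] + ev$duration[i])
    reg <- numeric(nf)
    for (t in seq_len(nf))
      for (l in seq_len(min(t, length(h))))
        reg[t] <- reg[t] + stim[t - l + 1] * h[l]
    coef <- cfg$pattern_amplitude *
      (gt$patterns[, ev$trial_type[i]] + cfg$common_activation)
    expected[gt$active_vertices, ] <- expected[gt$active_vertices, ] +
      outer(coef, reg)
  }
  expect_equal(max(abs(run$data - expected)), 0, tolerance = 1e-10)
  # inactive vertices carry nothing in the noiseless world
  inactive <- setdiff(seq_len(cfg$n_vertices), gt$active_vertices)
  expect_true(all(run$data[inactive, ] == 0))
})

test_that("task runs are deterministic and amplitude 0 removes all movement signal", {
  cfg <- small_cfg()
  gt <- make_ground_truth(cfg)
  ev <- make_design(cfg, 1L)
  r1 <- simulate_task_run(cfg, gt, ev, 9L)
  r2 <- simulate_task_run(cfg, gt, ev, 9L)
  expect_identical(r1$data, r2$data)
  # with amplitude 0, data are independent of the pattern geometry
  cfg_a <- small_cfg(pattern_amplitude = 0)
  cfg_b <- small_cfg(pattern_amplitude = 0, ecological_similarity = 0,
                     control_similarity = 0)
  ra <- simulate_task_run(cfg_a, make_ground_truth(cfg_a), ev, 9L)
  rb <- simulate_task_run(cfg_b, make_ground_truth(cfg_b), ev, 9L)
  expect_identical(ra$data, rb$data)
})

test_that("rest runs embed a Poisson event process with the configured rates", {
  cfg <- small_cfg(rest_event_rate_per_min = c(Grip = 4, Extend = 0,
                                               Pinch = 0, Shake = 0.5))
  gt <- make_ground_truth(cfg)
  # zero rates -> no events at all
  cfg0 <- small_cfg(rest_event_rate_per_min = c(Grip = 0, Extend = 0,
                                                Pinch = 0, Shake = 0))
  r0 <- simulate_rest_run(cfg0, make_ground_truth(cfg0), "pre", 3L)
  expect_equal(nrow(r0$events), 0L)
  # post-phase rates default to zero
  rp <- simulate_rest_run(cfg, gt, "post", 3L)
  expect_equal(nrow(rp$events), 0L)
  # event onsets lie inside the run
  r <- simulate_rest_run(cfg, gt, "pre", 3L)
  nf <- ncol(r$ts$data)
  expect_true(all(r$events$onset_frame >= 0 & r$events$onset_frame < nf))
  # empirical mean Grip count over seeds within 3 standard errors of
  # rate x duration (Poisson law: mean = var = lambda)
  lambda <- 4 * cfg$rest_run_duration_s / 60
  counts <- vapply(1:60, function(s)
    sum(simulate_rest_run(cfg, gt, "pre", s)$events$movement == "Grip"),
    numeric(1))
  se <- sqrt(lambda / 60)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # determinism
  expect_identical(simulate_rest_run(cfg, gt, "pre", 3L)$ts$data, r$ts$data)
})

test_that("simulate_subject produces the full consistent bundle", {
  cfg <- small_cfg()
  b <- simulate_subject(cfg)
  expect_length(b$task_runs, 5L)
  expect_length(b$task_events, 5L)
  expect_length(b$rest_pre, 2L)
  expect_length(b$rest_post, 2L)
  nvert <- vapply(c(b$task_runs, b$rest_pre, b$rest_post),
                  function(t) nrow(t$data), integer(1))
  expect_true(all(nvert == cfg$n_vertices))
  expect_true(all(b$rest_event_log$movement %in% MOVEMENTS))
  # a TR of 2 s halves the frame count for equal durations
  cfg2 <- small_cfg(tr_seconds = 2)
  b2 <- simulate_subject(cfg2)
  expect_equal(ncol(b2$rest_pre[[1]]$data),
               ncol(b$rest_pre[[1]]$data) / 2L)
  # same master seed -> byte-identical on-disk outputs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_subject(cfg, out_dir = d1)
  simulate_subject(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
})
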