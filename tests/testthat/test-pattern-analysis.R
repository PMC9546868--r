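test_that("block windows select the 10-18 s post-onset frames", {
  set.seed(3)
  m <- matrix(rnorm(6 * 60), 6, 60)
  ts <- ts_from(m)
  ev <- event_table(onset = 20, duration = 10, trial_type = "Pinch")
  bp <- extract_block_patterns(list(ts), list(ev), roi = 1:6)
  expect_equal(bp$window_frames, 8L)
  expect_equal(bp$frames[[1]], m[, 31:38]) # frame times 30..37 s
  expect_equal(bp$means[, 1], rowMeans(m[, 31:38]))
  # TR of 2 s -> floor(8 / 2) = 4 frames
  ts2 <- ts_from(m[, 1:30], tr = 2)
  bp2 <- extract_block_patterns(list(ts2), list(ev), roi = 1:6)
  expect_equal(bp2$window_frames, 4L)
  expect_equal(bp2$frames[[1]], m[, 16:19]) # times 30, 32, 34, 36 s
  # identical frames in the window -> mean equals any one frame
  m3 <- m; for (j in 31:38) m3[, j] <- m[, 31]
  bp3 <- extract_block_patterns(list(ts_from(m3)), list(ev), 1:6)
  expect_equal(bp3$means[, 1], m[, 31])
  # block window past the run end is skipped with a warning
  ev_late <- event_table(onset = c(20, 50), duration = c(10, 10),
                         trial_type = c("Grip", "Shake"))
  expect_warning(bp4 <- extract_block_patterns(list(ts), list(ev_late), 1:6),
                 "skipped")
  expect_equal(length(bp4$labels), 1L)
})

test_that("mean patterns average blocks and concatenate the window vertex-major", {
  ca <- cached_subject_analysis()
  pat <- ca$res$patterns
  nroi <- length(ca$res$roi$vertex_ids)
  expect_equal(dim(pat$spatial), c(nroi, 4L))
  expect_equal(dim(pat$spatiotemporal), c(nroi * 8L, 4L))
  # full-scale arithmetic of the concatenated length
  expect_equal(2187 * 8, 17496)
  # spatio-temporal layout: frame k of the mean window sits at rows
  # (k-1)*|roi| + 1 ... k*|roi|, consistent with matrix column-major flattening
  bp <- extract_block_patterns(ca$res$task_pp, ca$res$events,
                               ca$res$roi$vertex_ids)
  grip <- bp$frames[bp$labels == "Grip"]
  mean_win <- Reduce(`+`, grip) / length(grip)
  expect_equal(pat$spatiotemporal[, "Grip"], as.vector(mean_win))
  expect_equal(unname(pat$spatiotemporal[(3 - 1) * nroi + 5, "Grip"]),
               mean_win[5, 3])
  # a movement with no blocks is an error
  bp_miss <- bp; bp_miss$labels[bp_miss$labels == "Shake"] <- "Grip"
  expect_error(compute_mean_patterns(bp_miss), "Shake")
})

test_that("noiseless subjects recover the ground-truth patterns (r >= 0.99)", {
  cfg <- small_cfg(noise_sd = 0, global_noise_sd = 0)
  b <- simulate_subject(cfg)
  roi <- b$ground_truth$active_vertices
  raw <- lapply(b$task_runs, drop_initial_frames)
  ev <- lapply(b$task_events, realign_events)
  # GSR is skipped: in a noiseless world the global signal is collinear with
  # the evoked response itself; rest-gap frames are flat and get excluded
  pp <- suppressWarnings(lapply(raw, zscore_frames, roi = roi))
  pat <- compute_mean_patterns(extract_block_patterns(pp, ev, roi))
  for (m in MOVEMENTS)
    expect_gte(cor(pat$spatial[, m], b$ground_truth$patterns[, m]), 0.99)
})

test_that("RSA reproduces the pattern-similarity geometry", {
  ca <- cached_subject_analysis()
  R <- rsa_matrix(ca$res$patterns)
  expect_equal(dim(R), c(4L, 4L))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_equal(R, t(R))
  # ecological movements mutually more similar than any is to Shake
  eco_pairs <- c(R["Grip", "Extend"], R["Grip", "Pinch"], R["Extend", "Pinch"])
  shake_pairs <- R[ECOLOGICAL <- c("Grip", "Extend", "Pinch"), "Shake"]
  expect_gt(mean(eco_pairs), mean(shake_pairs))
  # orthogonal ground-truth patterns -> off-diagonals ~ 0
  gt0 <- make_ground_truth(small_cfg(ecological_similarity = 0,
                                     control_similarity = 0))
  fake <- structure(list(spatial = gt0$patterns, window = c(10, 18),
                         window_frames = 8L), class = "movement_patterns")
  expect_lt(max(abs(rsa_matrix(fake)[upper.tri(diag(4))])), 1e-8)
  # zero-variance pattern errors
  fake$spatial[, 2] <- 1
  expect_error(rsa_matrix(fake), "zero-variance")
})

test_that("shrinkage LDA matches the hand-solved pooled-covariance solution", {
  # separable two-class problem: means +/- e1, tiny isotropic noise
  set.seed(7)
  x <- rbind(cbind(rnorm(20, 1, 0.01), rnorm(20, 0, 0.01)),
             cbind(rnorm(20, -1, 0.01), rnorm(20, 0, 0.01)))
  y <- rep(c("A", "B"), each = 20)
  fit <- lda_fit(x, y)
  expect_identical(predict(fit, x), y)
  # boundary perpendicular to e1: the discriminant difference loads on dim 1
  B <- predict(fit, diag(2), type = "score")
  d <- (B[, "A"] - B[, "B"])
  expect_gt(abs(d[1]), 100 * abs(d[2]))
  # worked 2-feature example with shrinkage 0 vs explicit normal equations
  xa <- matrix(c(0, 0, 1, 1, 1, 0, 3, 1, 4, 0, 4, 1), ncol = 2, byrow = TRUE)
  ya <- rep(c("A", "B"), each = 3)
  fit0 <- lda_fit(xa, ya, lambda = 0)
  mA <- colMeans(xa[1:3, ]); mB <- colMeans(xa[4:6, ])
  Xc <- rbind(sweep(xa[1:3, ], 2, mA), sweep(xa[4:6, ], 2, mB))
  S <- t(Xc) %*% Xc / (6 - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2) / det_s
  w_hand <- Sinv %*% (mA - mB)
  sc <- predict(fit0, diag(2), type = "score")
  w_fit <- sc[, "A"] - sc[, "B"]
  sc0 <- predict(fit0, rbind(c(0, 0)), type = "score")
  expect_equal(unname(w_fit - (sc0[, "A"] - sc0[, "B"])), as.numeric(w_hand),
               tolerance = 1e-10)
  # degenerate classes error
  expect_error(lda_fit(xa, c("A", rep("B", 5))), "at least 2")
  expect_error(lda_fit(xa, rep("A", 6)), "2 classes")
})

test_that("Woodbury and direct covariance-inverse routes agree when p > n", {
  set.seed(11)
  x <- matrix(rnorm(20 * 50), 20, 50)
  y <- rep(c("A", "B", "C", "D"), each = 5)
  fit <- lda_fit(x, y, lambda = 0.4)
  # direct route: form the p x p shrunk covariance explicitly
  M <- fit$means
  S <- crossprod(fit$Xc) / fit$df
  Sigma <- 0.6 * S + 0.4 * diag(diag(S))
  B_direct <- solve(Sigma, M)
  z <- matrix(rnorm(3 * 50), 3, 50)
  sc <- predict(fit, z, type = "score")
  const <- -0.5 * colSums(M * B_direct)
  expect_equal(unname(sc), unname(sweep(z %*% B_direct, 2, const, `+`)),
               tolerance = 1e-8)
})

test_that("leave-run-out decoding tracks the hemodynamic time course", {
  ca <- cached_subject_analysis()
  cv <- ca$res$classification
  expect_equal(sum(cv$confusion), 4) # rows sum to 1
  expect_equal(unname(rowSums(cv$confusion)), rep(1, 4))
  expect_equal(length(cv$per_tr_accuracy), 28L)
  # high-SNR default subject: near-ceiling inside the 10-18 s window,
  # chance at block onset (HRF onset delay)
  expect_gt(mean(cv$per_tr_accuracy[11:18]), 0.9)
  expect_lt(cv$per_tr_accuracy[1], 0.6)
  expect_gt(cv$mean_pattern_accuracy, 0.9)
  # accuracy time course correlates with the mean BOLD time course
  tc <- mean_bold_timecourse(lapply(ca$bundle$task_runs, drop_initial_frames),
                             ca$res$events, ca$res$roi)
  expect_gt(spearman(cv$per_tr_accuracy, colMeans(tc)), 0.7)
  # cross-validation hygiene: the held-out run never appears in training
  for (f in cv$folds) expect_false(f$held_out %in% f$train_runs)
  expect_error(crossval_timecourse(ca$res$task_pp[1:2], ca$res$events[1:2],
                                   ca$res$roi$vertex_ids), "at least 3")
  # a training fold lacking a movement is skipped with a warning
  ev_broken <- ca$res$events
  for (r in 2:5)
    ev_broken[[r]] <- ev_broken[[r]][ev_broken[[r]]$trial_type != "Shake", ]
  expect_warning(
    cv2 <- crossval_timecourse(ca$res$task_pp, ev_broken, ca$res$roi$vertex_ids),
    "lack some movements")
  expect_lt(length(cv2$folds), 5L)
})

test_that("label-permuted training decodes at chance and errors stay ecological", {
  # moderate SNR so the classifier makes some errors
  run_cv <- function(seed, permute = FALSE) {
    cfg <- small_cfg(pattern_amplitude = 0.04, n_rest_runs_pre = 0,
                     n_rest_runs_post = 0, seed = seed)
    b <- simulate_subject(cfg)
    roi <- b$ground_truth$active_vertices
    ev <- lapply(b$task_events, realign_events)
    if (permute)
      withr::with_seed(seed, {
        ev <- lapply(ev, function(e) {
          e$trial_type <- sample(e$trial_type); e
        })
      })
    pp <- lapply(b$task_runs, function(t)
      zscore_frames(regress_global_signal(drop_initial_frames(t)), roi))
    crossval_timecourse(pp, ev, roi)
  }
  # permuted training labels: accuracy ~ chance (0.25)
  accs <- sapply(21:23, function(s) mean(run_cv(s, permute = TRUE)$per_tr_accuracy))
  expect_lt(abs(mean(accs) - 0.25), 0.05)
  # misclassifications concentrate among the three ecological movements:
  # pooled over subjects, P(predicted ecological | performed ecological, error)
  # exceeds the 2/3 share that indifferent errors would give
  conf <- Reduce(`+`, lapply(21:23, function(s) run_cv(s)$confusion))
  eco <- c("Grip", "Extend", "Pinch")
  err_eco <- sum(sapply(eco, function(m) sum(conf[m, setdiff(eco, m)]))) /
    sum(sapply(eco, function(m) sum(conf[m, setdiff(MOVEMENTS, m)])))
  expect_gt(err_eco, 2 / 3)
})

test_that("mean BOLD time courses are percent signal change with equal peaks", {
  # constant run -> 0% everywhere
  ts <- ts_from(matrix(50, 4, 80))
  ev <- event_table(20, 10, "Grip")
  tc0 <- mean_bold_timecourse(list(ts), list(ev), roi = 1:4)
  expect_true(all(tc0["Grip", ] == 0))
  expect_true(all(is.na(tc0[c("Extend", "Pinch", "Shake"), ]))) # no blocks
  # noiseless single block: curve proportional to the convolved boxcar
  cfg <- small_cfg(noise_sd = 0, global_noise_sd = 0)
  gt <- make_ground_truth(cfg)
  ev1 <- event_table(20, 10, "Extend")
  attr(ev1, "run_duration_s") <- 80
  run <- simulate_task_run(cfg, gt, ev1, 1L)
  tc1 <- mean_bold_timecourse(list(run), list(ev1), gt$active_vertices)
  hrf <- make_hrf(1)
  stim <- as.numeric(0:79 >= 20 & 0:79 < 30)
  reg <- convolve(stim, rev(hrf), type = "open")[21:48]
  expect_gt(cor(tc1["Extend", ], reg), 0.999)
  expect_true(all(is.na(tc1[c("Grip", "Pinch", "Shake"), ])))
  # default subject: the four movements' peaks within 20% of each other
  ca <- cached_subject_analysis()
  tc <- mean_bold_timecourse(lapply(ca$bundle$task_runs, drop_initial_frames),
                             ca$res$events, ca$res$roi)
  peaks <- apply(tc, 1, max)
  expect_lt((max(peaks) - min(peaks)) / mean(peaks), 0.2)
  expect_error(mean_bold_timecourse(list(ts), list(event_table(0, 79, "Grip")),
                                    1:4), "baseline")
})
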