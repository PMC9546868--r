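#' Extract per-block activation patterns
#'
#' For each task block, collects the preprocessed (z-scored) frames whose time
#' relative to block onset lies in `[window[1], window[2])` seconds — by
#' default the most activated period 10-18 s after block onset — restricted to
#' the ROI vertices, and averages them into a per-block mean pattern. Blocks
#' whose window extends past the end of the run (or hits excluded frames) are
#' skipped with a warning.
#'
#' @param runs list of preprocessed [vertex_ts()] task runs.
#' @param events list of matching [event_table()]s (onsets already realigned
#'   to the retained frames).
#' @param roi integer vertex indices or a [select_roi()] result.
#' @param window numeric `c(start, end)` in seconds after block onset,
#'   half-open.
#' @return list of class `block_patterns`: `means` (|roi| x blocks matrix),
#'   `frames` (list of |roi| x window-frame matrices), `labels`, `run`,
#'   `window`, `window_frames`.
#' @export
extract_block_patterns <- function(runs, events, roi, window = c(10, 18)) {
  roi <- roi_indices(roi)
  stopifnot(length(runs) == length(events))
  wf <- floor((window[2] - window[1]) / runs[[1]]$tr_seconds)
  means <- list(); frames <- list(); labels <- character(0); run_ids <- character(0)
  for (r in seq_along(runs)) {
    ts <- runs[[r]]; ev <- events[[r]]
    expected_t <- function(onset)
      onset + window[1] + (seq_len(wf) - 1) * ts$tr_seconds
    for (i in seq_len(nrow(ev))) {
      want <- expected_t(ev$onset[i])
      idx <- match(round(want, 9), round(ts$frame_times, 9))
      if (anyNA(idx)) {
        warning(sprintf("run '%s': block %d (%s) window incomplete; skipped",
                        ts$run_id, i, ev$trial_type[i]), call. = FALSE)
        next
      }
      blk <- ts$data[roi, idx, drop = FALSE]
      means[[length(means) + 1L]] <- rowMeans(blk)
      frames[[length(frames) + 1L]] <- blk
      labels <- c(labels, ev$trial_type[i])
      run_ids <- c(run_ids, ts$run_id)
    }
  }
  if (!length(means)) stop("no complete blocks found", call. = FALSE)
  structure(list(means = do.call(cbind, means), frames = frames,
                 labels = labels, run = run_ids,
                 window = window, window_frames = wf),
            class = "block_patterns")
}

roi_indices <- function(roi) {
  if (inherits(roi, "roi_definition")) roi$vertex_ids else as.integer(roi)
}

#' Mean spatial and spatio-temporal movement patterns
#'
#' Averages block patterns over all of a movement's blocks across runs. The
#' spatial pattern is the mean of the per-block window-mean patterns; the
#' spatio-temporal pattern averages each window frame across blocks and
#' concatenates the frames into one vector (element for vertex v, window frame
#' k at position `(k-1) * |roi| + v`).
#'
#' @param block_patterns an [extract_block_patterns()] result.
#' @return list of class `movement_patterns`: `spatial` (|roi| x 4),
#'   `spatiotemporal` ((|roi| * window_frames) x 4), `window`,
#'   `window_frames`, `n_blocks` (per movement).
#' @export
compute_mean_patterns <- function(block_patterns) {
  bp <- block_patterns
  missing <- setdiff(MOVEMENTS, bp$labels)
  if (length(missing))
    stop("no blocks for movement(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  spatial <- vapply(MOVEMENTS, function(m)
    rowMeans(bp$means[, bp$labels == m, drop = FALSE]),
    numeric(nrow(bp$means)))
  st <- vapply(MOVEMENTS, function(m) {
    stack <- bp$frames[bp$labels == m]
    as.vector(Reduce(`+`, stack) / length(stack))
  }, numeric(nrow(bp$means) * bp$window_frames))
  structure(list(spatial = spatial, spatiotemporal = st,
                 window = bp$window, window_frames = bp$window_frames,
                 n_blocks = table(factor(bp$labels, MOVEMENTS))),
            class = "movement_patterns")
}

#' Representational similarity matrix of the four mean patterns
#'
#' @param patterns a [compute_mean_patterns()] result.
#' @return symmetric 4 x 4 Pearson correlation matrix (unit diagonal).
#' @export
rsa_matrix <- function(patterns) {
  X <- patterns$spatial
  if (any(apply(X, 2L, stats::sd) < .Machine$double.eps^0.5))
    stop("zero-variance mean pattern; RSA undefined", call. = FALSE)
  stats::cor(X)
}

#' Fit a shrinkage linear discriminant classifier
#'
#' LDA with the pooled within-class covariance shrunk toward its diagonal,
#' `Sigma = (1 - lambda) S + lambda diag(S)`, which keeps the classifier well
#' posed when features (vertices) far outnumber training samples. The
#' shrinkage intensity is chosen analytically (Ledoit-Wolf/Schafer-Strimmer
#' style: ratio of the summed sampling variances of the off-diagonal
#' covariances to their summed squares), computed without ever forming the
#' p x p covariance. Priors are equal; prediction is by highest discriminant
#' score with ties broken toward the lowest class index.
#'
#' @param x numeric matrix, samples x features.
#' @param labels class labels (factor or character); class order follows
#'   factor levels.
#' @param lambda optional shrinkage in `[0, 1]`; `NULL` (default) = analytic.
#' @return an object of class `lda_shrink`.
#' @export
lda_fit <- function(x, labels, lambda = NULL) {
  x <- as.matrix(x)
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels, unique(labels))
  if (nlevels(f) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(f)
  if (any(counts < 2L))
    stop("every class needs at least 2 training samples", call. = FALSE)
  n <- nrow(x); k <- nlevels(f); p <- ncol(x); df <- n - k
  M <- vapply(levels(f), function(l)
    colMeans(x[f == l, , drop = FALSE]), numeric(p)) # p x k
  Xc <- x - t(M)[as.integer(f), , drop = FALSE]      # class-centered
  d <- colSums(Xc^2) / df                            # diag of pooled covariance
  d <- pmax(d, .Machine$double.eps)
  if (is.null(lambda)) lambda <- shrinkage_intensity(Xc, df)
  stopifnot(lambda >= 0, lambda <= 1)
  structure(list(means = M, Xc = Xc, d = d, lambda = lambda,
                 levels = levels(f), n = n, k = k, df = df),
            class = "lda_shrink")
}

# analytic shrinkage toward the diagonal, O(n^2 p): lambda* =
# sum_{i != j} Var(s_ij) / sum_{i != j} s_ij^2, clipped to [1e-4, 1]
shrinkage_intensity <- function(Xc, df) {
  n <- nrow(Xc)
  if (n < 3L) return(1)
  q <- rowSums(Xc^2)
  G <- sum(tcrossprod(Xc)^2)          # ||Xc' Xc||_F^2 via the n x n Gram
  D2 <- sum(colSums(Xc^2)^2)          # sum_i (sum_k x_ki^2)^2
  sum_w2 <- sum(q^2)                  # sum_ij sum_k w_kij^2
  qd <- colSums(Xc^4)
  var_all <- (sum_w2 - G / n) / (n - 1)
  var_diag <- (sum(qd) - D2 / n) / (n - 1)
  num <- n * max(var_all - var_diag, 0)
  den <- max(G - D2, .Machine$double.eps)
  min(max(num / den, 1e-4), 1)
}

#' @export
print.lda_shrink <- function(x, ...) {
  cat(sprintf("<lda_shrink> %d classes, %d samples, %d features, lambda = %.3g\n",
              x$k, x$n, length(x$d), x$lambda))
  invisible(x)
}

#' Predict classes with a shrinkage LDA model
#'
#' @param object an [lda_fit()] model.
#' @param newdata matrix, samples x features.
#' @param type `"class"` (default) or `"score"` (discriminant scores).
#' @param ... unused.
#' @return character vector of predicted labels, or a score matrix.
#' @export
predict.lda_shrink <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  Z <- as.matrix(newdata)
  if (is.null(dim(newdata)) && length(newdata) == length(object$d))
    Z <- matrix(newdata, 1L)
  B <- discriminant_directions(object)            # p x k
  const <- -0.5 * colSums(object$means * B)       # per class
  scores <- sweep(Z %*% B, 2L, const, `+`)
  colnames(scores) <- object$levels
  if (type == "score") return(scores)
  object$levels[apply(scores, 1L, which.max)]     # first max = lowest index
}

# B = Sigma^{-1} M where Sigma = lambda D + (1 - lambda)/df * Xc' Xc.
# Uses the Woodbury identity when p > n so cost is O(p n^2), never O(p^3).
discriminant_directions <- function(model) {
  M <- model$means; lam <- model$lambda; d <- model$d; df <- model$df
  p <- length(d); n <- model$n
  if (lam >= 1) return(M / d)
  if (p <= n) {
    Sigma <- (1 - lam) * crossprod(model$Xc) / df
    diag(Sigma) <- diag(Sigma) + lam * d
    return(solve(Sigma, M))
  }
  cc <- (1 - lam) / df
  ad <- lam * d
  AiM <- M / ad
  AiU <- t(model$Xc) / ad                         # p x n
  K <- model$Xc %*% AiU
  diag(K) <- diag(K) + 1 / cc
  AiM - AiU %*% solve(K, model$Xc %*% AiM)
}

#' Leave-one-run-out decoding of movements, frame by frame
#'
#' For each cross-validation fold, a shrinkage LDA is trained on the
#' block-mean window patterns of all runs but one, and every z-scored frame of
#' each held-out block is classified at each within-block frame index (frames
#' with `0 <= time - onset < test_window_s`). Per-index accuracy is aggregated
#' over blocks and folds. A mean-pattern variant classifies the held-out
#' blocks' window-mean patterns and accumulates the 4 x 4 confusion matrix
#' (rows: performed movement; entries: P(predicted | performed)).
#'
#' @param runs list of preprocessed [vertex_ts()] task runs.
#' @param events parallel list of realigned [event_table()]s.
#' @param roi vertex indices or [select_roi()] result.
#' @param window training window `c(start, end)` seconds after onset.
#' @param test_window_s length of the per-frame test window from block onset.
#' @param lambda optional fixed shrinkage (default analytic).
#' @return object of class `classification_result`: `per_tr_accuracy` (named
#'   by frame index), `per_tr_n`, `mean_pattern_accuracy`, `confusion`,
#'   `chance` (= 0.25), `folds` (per-fold bookkeeping: held-out run and
#'   training-run ids).
#' @export
crossval_timecourse <- function(runs, events, roi, window = c(10, 18),
                                test_window_s = 28, lambda = NULL) {
  roi <- roi_indices(roi)
  if (length(runs) < 3L) stop("need at least 3 runs for cross-validation",
                              call. = FALSE)
  tr <- runs[[1]]$tr_seconds
  n_idx <- floor(test_window_s / tr)
  hits <- matrix(0, 2L, n_idx, dimnames = list(c("correct", "total"), NULL))
  confusion <- matrix(0, 4L, 4L, dimnames = list(MOVEMENTS, MOVEMENTS))
  mp_correct <- 0L; mp_total <- 0L
  folds <- list()
  for (held in seq_along(runs)) {
    train_bp <- extract_block_patterns(runs[-held], events[-held], roi, window)
    if (length(unique(train_bp$labels)) < 4L) {
      warning(sprintf("fold %d: training runs lack some movements; skipped",
                      held), call. = FALSE)
      next
    }
    model <- lda_fit(t(train_bp$means),
                     factor(train_bp$labels, MOVEMENTS), lambda = lambda)
    folds[[length(folds) + 1L]] <-
      list(held_out = runs[[held]]$run_id,
           train_runs = unique(train_bp$run),
           lambda = model$lambda)
    ts <- runs[[held]]; ev <- events[[held]]
    for (i in seq_len(nrow(ev))) {
      rel <- ts$frame_times - ev$onset[i]
      in_win <- which(rel >= 0 & rel < test_window_s)
      if (length(in_win)) {
        pred <- predict(model, t(ts$data[roi, in_win, drop = FALSE]))
        j <- floor(rel[in_win] / tr) + 1L
        ok <- pred == ev$trial_type[i]
        for (u in seq_along(j)) {
          hits["total", j[u]] <- hits["total", j[u]] + 1
          hits["correct", j[u]] <- hits["correct", j[u]] + ok[u]
        }
      }
    }
    # mean-pattern variant on the held-out run's block means
    test_bp <- tryCatch(
      extract_block_patterns(runs[held], events[held], roi, window),
      error = function(e) NULL)
    if (!is.null(test_bp)) {
      pred <- predict(model, t(test_bp$means))
      for (u in seq_along(pred)) {
        confusion[test_bp$labels[u], pred[u]] <-
          confusion[test_bp$labels[u], pred[u]] + 1
        mp_total <- mp_total + 1L
        mp_correct <- mp_correct + (pred[u] == test_bp$labels[u])
      }
    }
  }
  if (!length(folds)) stop("all folds were skipped", call. = FALSE)
  rs <- rowSums(confusion) # blocks per performed movement
  conf_norm <- sweep(confusion, 1L, pmax(rs, 1L), `/`)
  acc <- hits["correct", ] / pmax(hits["total", ], 1L)
  names(acc) <- seq_len(n_idx) - 1L
  structure(list(per_tr_accuracy = acc, per_tr_n = hits["total", ],
                 mean_pattern_accuracy = mp_correct / max(mp_total, 1L),
                 confusion = conf_norm, chance = 0.25, folds = folds),
            class = "classification_result")
}

#' Group-level inference on per-frame accuracy curves
#'
#' One-sample t-test of per-index accuracy against chance across subjects,
#' with Benjamini-Hochberg FDR correction across frame indices.
#'
#' @param acc matrix, subjects x frame indices.
#' @param chance chance level (default 0.25).
#' @param q FDR level.
#' @return data.frame: `frame_index`, `mean_accuracy`, `t`, `df`, `p_raw`,
#'   `p_significant_fdr`.
#' @export
accuracy_group_inference <- function(acc, chance = 0.25, q = 0.05) {
  acc <- as.matrix(acc)
  n <- nrow(acc)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  tstat <- apply(acc, 2L, function(a) {
    s <- stats::sd(a)
    if (s < .Machine$double.eps^0.5) return(NA_real_)
    (mean(a) - chance) / (s / sqrt(n))
  })
  p <- 2 * stats::pt(-abs(tstat), n - 1L)
  p_eff <- ifelse(is.na(p), 1, p)
  rej <- fdr_bh(p_eff, q = q)$reject
  data.frame(frame_index = seq_len(ncol(acc)) - 1L,
             mean_accuracy = colMeans(acc),
             t = tstat, df = n - 1L, p_raw = p,
             p_significant_fdr = rej)
}

#' Mean BOLD percent-signal-change time course per movement
#'
#' Computed on raw (non-GSR, non-z-scored, frames-dropped) data: for each
#' movement and within-block frame index, the mean over ROI vertices and
#' blocks of `(signal - baseline) / baseline * 100`, where the baseline is the
#' ROI-mean signal over all frames lying outside every block-plus-HRF-tail
#' window.
#'
#' @param runs list of raw [vertex_ts()] task runs (after frame dropping).
#' @param events parallel list of realigned [event_table()]s.
#' @param roi vertex indices or [select_roi()] result.
#' @param test_window_s time-course length from block onset (s).
#' @param hrf_tail_s response tail appended to each block when defining
#'   baseline frames (default `2.25 + 10 * 1.25`).
#' @return matrix, 4 movements x frame indices, percent signal change.
#' @export
mean_bold_timecourse <- function(runs, events, roi, test_window_s = 28,
                                 hrf_tail_s = 2.25 + 10 * 1.25) {
  roi <- roi_indices(roi)
  tr <- runs[[1]]$tr_seconds
  n_idx <- floor(test_window_s / tr)
  base_vals <- c()
  sums <- matrix(0, 4L, n_idx, dimnames = list(MOVEMENTS, NULL))
  counts <- matrix(0, 4L, n_idx, dimnames = list(MOVEMENTS, NULL))
  for (r in seq_along(runs)) {
    ts <- runs[[r]]; ev <- events[[r]]
    roi_mean <- colMeans(ts$data[roi, , drop = FALSE])
    in_any <- rep(FALSE, length(ts$frame_times))
    for (i in seq_len(nrow(ev)))
      in_any <- in_any | (ts$frame_times >= ev$onset[i] &
                          ts$frame_times < ev$onset[i] + ev$duration[i] + hrf_tail_s)
    base_vals <- c(base_vals, roi_mean[!in_any])
    for (i in seq_len(nrow(ev))) {
      rel <- ts$frame_times - ev$onset[i]
      sel <- which(rel >= 0 & rel < test_window_s)
      j <- floor(rel[sel] / tr) + 1L
      m <- ev$trial_type[i]
      sums[m, j] <- sums[m, j] + roi_mean[sel]
      counts[m, j] <- counts[m, j] + 1
    }
  }
  if (!length(base_vals)) stop("no baseline frames outside block windows",
                               call. = FALSE)
  baseline <- mean(base_vals)
  if (baseline <= 0)
    stop("non-positive baseline; percent signal change undefined", call. = FALSE)
  pct <- (sums / pmax(counts, 1L) - baseline) / baseline * 100
  pct[counts == 0] <- NA_real_ # movement x index cells never sampled
  colnames(pct) <- seq_len(n_idx) - 1L
  pct
}
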