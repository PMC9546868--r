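#' Build a GLM design matrix for one run
#'
#' Columns: intercept; a single combined task regressor (sum over all blocks,
#' movements pooled, of the block boxcar convolved with the HRF — pooling all
#' four movements avoids biasing ROI selection toward any one of them); a
#' linear drift term; optionally one regressor per movement (diagnostics) and
#' user-supplied nuisance regressors (e.g. motion parameters).
#'
#' @param events an [event_table()].
#' @param hrf sampled HRF kernel from [make_hrf()] (same TR).
#' @param n_frames number of frames in the run.
#' @param tr repetition time (s).
#' @param nuisance optional numeric matrix (`n_frames` rows) of nuisance
#'   regressors.
#' @param per_movement include one convolved regressor per movement.
#' @return numeric `n_frames` x k matrix with named columns
#'   (`intercept`, `task`, `drift`, ...).
#' @export
build_design_matrix <- function(events, hrf, n_frames, tr,
                                nuisance = NULL, per_movement = FALSE) {
  validate_events(events)
  assert_count(n_frames)
  ft <- (seq_len(n_frames) - 1) * tr
  if (nrow(events) && max(events$onset + events$duration) > n_frames * tr)
    stop("event windows extend past the run duration", call. = FALSE)
  conv_for <- function(rows) {
    stim <- rep(0, n_frames)
    for (i in rows)
      stim[ft >= events$onset[i] & ft < events$onset[i] + events$duration[i]] <- 1
    convolve_hrf(stim, hrf)
  }
  X <- cbind(intercept = 1,
             task = conv_for(seq_len(nrow(events))),
             drift = seq(0, 1, length.out = n_frames))
  if (per_movement)
    for (m in MOVEMENTS) {
      col <- conv_for(which(events$trial_type == m))
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("task_", m)
    }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_frames)
      stop("nuisance regressors must have n_frames rows", call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  check_design_rank(X)
  X
}

check_design_rank <- function(X) {
  # all-zero regressors (e.g. a task column with no events) are permitted in a
  # constructed design; collinearity among the informative columns is not
  nonzero <- which(colSums(abs(X)) > 0)
  qrx <- qr(X[, nonzero, drop = FALSE])
  if (qrx$rank < length(nonzero)) {
    dropped <- colnames(X)[nonzero][qrx$pivot[(qrx$rank + 1L):length(nonzero)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(X)
}

#' Fit a mass-univariate GLM
#'
#' Ordinary least squares per vertex, with a t statistic and two-tailed p for
#' the combined task regressor (task vs baseline contrast). Multiple runs are
#' concatenated with per-run intercept and drift columns (columns named
#' `intercept` or `drift` are given one block per run; all other columns are
#' stacked and shared across runs).
#'
#' @param ts a [vertex_ts()] or list of them (one per run).
#' @param design design matrix from [build_design_matrix()], or a parallel
#'   list of per-run design matrices.
#' @param contrast name of the tested column (default `"task"`).
#' @return an object of class `glm_fit`: `betas` (vertices x regressors),
#'   `contrast_t`, `contrast_p`, `df`, `design`, `contrast`.
#' @export
fit_glm <- function(ts, design, contrast = "task") {
  if (inherits(ts, "vertex_ts")) { ts <- list(ts); design <- list(design) }
  stopifnot(length(ts) == length(design))
  nfr <- vapply(ts, n_frames, integer(1))
  for (r in seq_along(ts))
    if (nrow(design[[r]]) != nfr[r])
      stop(sprintf("run %d: design has %d rows but data %d frames",
                   r, nrow(design[[r]]), nfr[r]), call. = FALSE)
  X <- concat_designs(design)
  Y <- t(do.call(cbind, lapply(ts, `[[`, "data"))) # frames x vertices
  if (nrow(X) <= ncol(X))
    stop("fewer frames than regressors", call. = FALSE)
  check_design_rank(X)
  fit <- stats::lm.fit(X, Y)
  betas <- t(fit$coefficients)
  df <- nrow(X) - qr(X)$rank
  sigma2 <- colSums(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  ci <- match(contrast, colnames(X))
  if (is.na(ci)) stop("no '", contrast, "' column in design", call. = FALSE)
  se <- sqrt(sigma2 * XtXinv[ci, ci])
  tstat <- betas[, ci] / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1] for log-scale search
  structure(list(betas = betas, contrast_t = tstat, contrast_p = p,
                 df = df, design = X, contrast = contrast),
            class = "glm_fit")
}

concat_designs <- function(designs) {
  if (length(designs) == 1L) return(designs[[1L]])
  per_run <- c("intercept", "drift")
  shared_cols <- setdiff(colnames(designs[[1L]]), per_run)
  nfr <- vapply(designs, nrow, integer(1))
  total <- sum(nfr)
  shared <- do.call(rbind, lapply(designs, function(d) d[, shared_cols, drop = FALSE]))
  blocks <- list()
  for (r in seq_along(designs)) {
    b <- matrix(0, total, length(per_run),
                dimnames = list(NULL, paste0(per_run, "_run", r)))
    rows <- seq.int(sum(nfr[seq_len(r - 1L)]) + 1L, sum(nfr[seq_len(r)]))
    b[rows, ] <- designs[[r]][, per_run]
    blocks[[r]] <- b
  }
  X <- cbind(shared, do.call(cbind, blocks))
  # keep a plain "intercept" alias out; contrast columns retain their names
  X
}

#' Adaptive-threshold ROI selection
#'
#' Finds a p-threshold for the task-vs-baseline contrast such that the number
#' of selected vertices (candidate-mask vertices with `contrast_p` below the
#' threshold AND positive task beta) is within `tolerance * target_size` of
#' `target_size`. The threshold is searched by bisection on log10(p) over
#' `[1e-12, 0.05]` (ROI size is non-decreasing in the threshold); bisection
#' runs to convergence and keeps the threshold whose count lies closest to the
#' target. If the tolerance is unattainable the closest achievable set is
#' returned with `achieved = FALSE` and a warning.
#'
#' @param glm a [fit_glm()] result.
#' @param candidate_mask vertex indices to search within.
#' @param target_size desired ROI size in vertices (default 2187).
#' @param tolerance acceptable fractional deviation (default 0.07).
#' @param max_iter bisection iteration cap.
#' @return an object of class `roi_definition`: `vertex_ids`, `p_threshold`,
#'   `size`, `target_size`, `tolerance`, `achieved`.
#' @export
select_roi <- function(glm, candidate_mask, target_size = 2187,
                       tolerance = 0.07, max_iter = 60L) {
  stopifnot(inherits(glm, "glm_fit"))
  assert_count(target_size)
  if (length(candidate_mask) < target_size) {
    warning("candidate mask smaller than target size; ROI sizing infeasible",
            call. = FALSE)
    return(roi_result(glm, candidate_mask, 0.05, target_size, tolerance, FALSE))
  }
  p <- glm$contrast_p[candidate_mask]
  pos <- glm$betas[candidate_mask, glm$contrast] > 0
  count_at <- function(log10p) sum(p < 10^log10p & pos)
  tol_n <- tolerance * target_size
  lo <- -12; hi <- log10(0.05)
  n_lo <- count_at(lo); n_hi <- count_at(hi)
  if (n_hi < target_size - tol_n || n_lo > target_size + tol_n) {
    warning(sprintf(
      "ROI size %d +/- %.0f unattainable in [1e-12, 0.05] (achievable range %d..%d)",
      target_size, tol_n, n_lo, n_hi), call. = FALSE)
    thr <- if (abs(n_hi - target_size) < abs(n_lo - target_size)) hi else lo
    return(roi_result(glm, candidate_mask, 10^thr, target_size, tolerance, FALSE))
  }
  best <- if (abs(n_hi - target_size) < abs(n_lo - target_size)) hi else lo
  best_n <- count_at(best)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    n_mid <- count_at(mid)
    if (abs(n_mid - target_size) < abs(best_n - target_size)) {
      best <- mid; best_n <- n_mid
    }
    if (n_mid == target_size) break
    if (n_mid > target_size) hi <- mid else lo <- mid
  }
  achieved <- abs(best_n - target_size) <= tol_n
  if (!achieved)
    warning("bisection did not reach tolerance; returning closest threshold",
            call. = FALSE)
  roi_result(glm, candidate_mask, 10^best, target_size, tolerance, achieved)
}

roi_result <- function(glm, candidate_mask, p_threshold, target_size,
                       tolerance, achieved) {
  sel <- candidate_mask[glm$contrast_p[candidate_mask] < p_threshold &
                          glm$betas[candidate_mask, glm$contrast] > 0]
  structure(list(vertex_ids = sort(sel), p_threshold = p_threshold,
                 size = length(sel), target_size = as.integer(target_size),
                 tolerance = tolerance, achieved = achieved),
            class = "roi_definition")
}

#' @export
print.roi_definition <- function(x, ...) {
  cat(sprintf("<roi_definition> %d vertices (target %d +/- %.0f%%) at p < %.3g%s\n",
              x$size, x$target_size, 100 * x$tolerance, x$p_threshold,
              if (x$achieved) "" else " [TARGET NOT ACHIEVED]"))
  invisible(x)
}
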