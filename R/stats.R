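#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition with subjects as a random factor:
#' `F = MS_condition / MS_(condition x subject)` with `df1 = k - 1` and
#' `df2 = (k - 1)(n - 1)`. No sphericity correction is applied.
#'
#' @param values numeric matrix, subjects x conditions (complete).
#' @return list of class `anova_result`: `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_1way <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells in the subject x condition table",
                          call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  grand <- mean(values)
  cond_means <- colMeans(values)
  subj_means <- rowMeans(values)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  Fstat <- (ss_cond / df1) / (ss_err / df2)
  structure(list(F = Fstat, df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE)),
            class = "anova_result")
}

#' Paired-sample t-test (two-tailed)
#'
#' @param a,b per-subject paired values (equal lengths, n >= 2).
#' @return list of class `ttest_result`: `t`, `df`, `p` (two-tailed),
#'   `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s < .Machine$double.eps^0.5)
    stop("zero-variance differences; t undefined", call. = FALSE)
  tstat <- mean(d) / (s / sqrt(n))
  structure(list(t = tstat, df = n - 1L,
                 p = 2 * stats::pt(-abs(tstat), n - 1L),
                 mean_diff = mean(d)),
            class = "ttest_result")
}

#' Holm-Bonferroni sequential correction
#'
#' Steps through the p-values in ascending order, rejecting `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)` and stopping at the first failure.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return list of class `correction_result`: `method`, `p_raw`, `reject`
#'   (logical, in input order), `alpha`, `order` (ascending-p permutation).
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  check_p(p_values)
  m <- length(p_values)
  o <- order(p_values)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[o[i]] <= alpha / (m - i + 1)) reject_sorted[i] <- TRUE
    else break
  }
  reject <- logical(m); reject[o] <- reject_sorted
  structure(list(method = "holm", p_raw = p_values, reject = reject,
                 alpha = alpha, order = o),
            class = "correction_result")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure: with p-values sorted ascending, reject all
#' `p <= p_(k*)` where `k* = max{k : p_(k) <= (k / m) q}`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list of class `correction_result` (as [holm_bonferroni()]).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  check_p(p_values)
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  k_ok <- which(ps <= seq_len(m) / m * q)
  reject <- logical(m)
  if (length(k_ok)) reject[o[seq_len(max(k_ok))]] <- TRUE
  structure(list(method = "bh_fdr", p_raw = p_values, reject = reject,
                 alpha = q, order = o),
            class = "correction_result")
}

check_p <- function(p) {
  if (!length(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho (scalar).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps^0.5 ||
      stats::sd(y) < .Machine$double.eps^0.5)
    stop("constant input; rank correlation undefined", call. = FALSE)
  stats::cor(rank(x), rank(y))
}

#' Group-level analysis of a cutoff table
#'
#' For each phase x variant cell of a multi-subject cutoff table: a one-way
#' repeated-measures ANOVA over the four movements, followed by the planned
#' post-hoc families of two-tailed paired t-tests with Holm-Bonferroni
#' correction within each family: (i) each ecological movement vs Shake within
#' the phase; (ii) pre vs post per movement (when both phases are present);
#' (iii) Grip vs Pinch, added for the spatio-temporal variant. Raw p-values
#' are reported alongside the correction decision.
#'
#' @param cutoffs data.frame as returned by [replay_summary()], rows from
#'   multiple subjects.
#' @param alpha family-wise error level for Holm correction.
#' @param grip_vs_pinch_variants variants for which the Grip-vs-Pinch contrast
#'   is added.
#' @return data.frame: `variant`, `phase`, `family`, `test`, `comparison`,
#'   `statistic`, `df1`, `df2`, `p_raw`, `significant_corrected`.
#' @export
analyze_experiment <- function(cutoffs, alpha = 0.05,
                               grip_vs_pinch_variants = "spatiotemporal_r2") {
  need <- c("subject", "movement", "phase", "variant", "cutoff")
  stopifnot(all(need %in% names(cutoffs)))
  subjects <- sort(unique(cutoffs$subject))
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  cell_matrix <- function(df, cols, col_field = "movement") {
    out <- sapply(cols, function(cc)
      sapply(subjects, function(s) {
        v <- df$cutoff[df[[col_field]] == cc & df$subject == s]
        if (length(v) == 1L) v else NA_real_
      }))
    out
  }
  run_family <- function(tests, variant, phase, family) {
    # tests: named list of paired value-matrices columns (a, b)
    res <- lapply(tests, function(ab) tryCatch(paired_t(ab[[1]], ab[[2]]),
                                               error = function(e) NULL))
    keep <- !vapply(res, is.null, logical(1))
    if (!any(keep)) return(invisible(NULL))
    res <- res[keep]
    hb <- holm_bonferroni(vapply(res, `[[`, numeric(1), "p"), alpha)
    for (i in seq_along(res))
      add(variant = variant, phase = phase, family = family,
          test = "paired_t", comparison = names(res)[i],
          statistic = res[[i]]$t, df1 = res[[i]]$df, df2 = NA_real_,
          p_raw = res[[i]]$p, significant_corrected = hb$reject[i])
  }
  for (variant in unique(cutoffs$variant)) {
    dv <- cutoffs[cutoffs$variant == variant, ]
    for (phase in intersect(c("pre", "post"), unique(dv$phase))) {
      dp <- dv[dv$phase == phase, ]
      tab <- cell_matrix(dp, MOVEMENTS)
      if (anyNA(tab)) {
        warning(sprintf("missing cells for variant %s phase %s; ANOVA skipped",
                        variant, phase), call. = FALSE)
        next
      }
      an <- rm_anova_1way(tab)
      add(variant = variant, phase = phase, family = "anova",
          test = "rm_anova", comparison = "movement",
          statistic = an$F, df1 = an$df1, df2 = an$df2, p_raw = an$p,
          significant_corrected = an$p < alpha)
      tests <- lapply(ECOLOGICAL, function(m)
        list(tab[, m], tab[, "Shake"]))
      names(tests) <- paste0(ECOLOGICAL, "_vs_Shake")
      if (variant %in% grip_vs_pinch_variants)
        tests$Grip_vs_Pinch <- list(tab[, "Grip"], tab[, "Pinch"])
      run_family(tests, variant, phase, "vs_control")
    }
    if (all(c("pre", "post") %in% dv$phase)) {
      pre_tab <- cell_matrix(dv[dv$phase == "pre", ], MOVEMENTS)
      post_tab <- cell_matrix(dv[dv$phase == "post", ], MOVEMENTS)
      if (!anyNA(pre_tab) && !anyNA(post_tab)) {
        tests <- lapply(MOVEMENTS, function(m)
          list(pre_tab[, m], post_tab[, m]))
        names(tests) <- paste0(MOVEMENTS, "_pre_vs_post")
        run_family(tests, variant, "pre_vs_post", "phase_change")
      }
    }
  }
  do.call(rbind, rows)
}
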