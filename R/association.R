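# Steps 1 and 2 of the testing procedure: the per-window one-way ANOVA
# filter across groups and the pairwise one-sided Welch t-tests that
# declare windows associated with a group.

#' Threshold set for the three-step testing procedure
#'
#' @param alpha1 significance threshold on Bonferroni-corrected ANOVA
#'   p-values (step 1; default 1e-10).
#' @param alpha2 significance threshold on raw one-sided t-test p-values
#'   (step 2; default 0.01).
#' @param m rejection-count threshold: a window is associated with group
#'   i when its signal is significantly higher than that of more than
#'   `m` other groups (default 14, i.e. all 15 comparisons among 16
#'   groups).
#' @param m_rule `"greater"` (strictly more than `m` rejections, the
#'   default) or `"geq"` (at least `m`).
#' @param step2_bonferroni apply a Bonferroni correction to the step-2
#'   p-values over the number of ordered group pairs (default FALSE:
#'   raw p-values are compared to `alpha2`).
#' @return list of class `"epom_thresholds"`.
#' @export
epom_thresholds <- function(alpha1 = 1e-10, alpha2 = 0.01, m = 14,
                            m_rule = c("greater", "geq"),
                            step2_bonferroni = FALSE) {
  if (alpha1 <= 0 || alpha1 > 1) stop("alpha1 must be in (0, 1]")
  if (alpha2 <= 0 || alpha2 > 1) stop("alpha2 must be in (0, 1]")
  if (m < 0) stop("m must be non-negative")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, m = as.integer(m),
                 m_rule = match.arg(m_rule),
                 step2_bonferroni = isTRUE(step2_bonferroni)),
            class = "epom_thresholds")
}

## Row-wise one-way fixed-effects ANOVA.  Returns the log10 p-value per
## row; degenerate rows follow the limits of the F statistic:
## zero within- and between-group variance -> p = 1; zero within-group
## variance with unequal means -> p = 0.
row_anova_log10p <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  G <- nlevels(groups)
  S <- length(groups)
  if (G < 2) stop("need at least 2 groups")
  ng <- as.vector(table(groups))
  if (any(ng < 2)) stop("every group needs >= 2 samples")
  ## indicator matrix S x G scaled to compute group means by one matmul
  ind <- stats::model.matrix(~ groups - 1)
  gm <- values %*% ind %*% diag(1 / ng, G)     # row group means
  overall <- rowMeans(values)
  ssb <- as.vector((gm - overall)^2 %*% ng)
  ssw <- rowSums(values^2) - as.vector(gm^2 %*% ng)
  ssw <- pmax(ssw, 0)  # guard tiny negative rounding
  dfb <- G - 1
  dfw <- S - G
  msw <- ssw / dfw
  f <- (ssb / dfb) / msw
  log10p <- stats::pf(f, dfb, dfw, lower.tail = FALSE,
                      log.p = TRUE) / log(10)
  ## degenerate rows
  eps <- .Machine$double.eps * S * pmax(rowMeans(values^2), 1)
  zero_w <- msw <= eps
  log10p[zero_w & ssb > eps] <- -Inf
  log10p[zero_w & ssb <= eps] <- 0
  log10p
}

#' Step 1: ANOVA filter for candidate associated windows
#'
#' Tests, per window, the null hypothesis that all group mean signals
#' are equal with a one-way fixed-effects ANOVA, Bonferroni-corrects the
#' p-values by the number of windows tested in the matrix, and keeps
#' windows with corrected p below `alpha1`.  P-values are handled in
#' log10 space so that deeply significant windows do not underflow.
#'
#' @param sm a `"signal_matrix"`.
#' @param thresholds an `"epom_thresholds"` (or a number, taken as
#'   `alpha1`).
#' @return list with `kept` (logical vector over windows), `windows`
#'   (the surviving window data frame), `log10p` (raw log10 p-values),
#'   `log10p_adj` (Bonferroni-corrected, capped at 0), `n_tested`.
#' @export
anova_filter <- function(sm, thresholds = epom_thresholds()) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (is.numeric(thresholds)) {
    thresholds <- epom_thresholds(alpha1 = thresholds)
  }
  groups <- matrix_groups(sm)
  log10p <- unname(row_anova_log10p(sm$values, groups))
  n <- nrow(sm$values)
  log10p_adj <- pmin(0, log10p + log10(n))
  kept <- log10p_adj < log10(thresholds$alpha1)
  list(kept = kept,
       windows = sm$windows[kept, , drop = FALSE],
       log10p = log10p,
       log10p_adj = log10p_adj,
       n_tested = n)
}

## One-sided Welch t-test log10 p-values for H0: mu_i <= mu_j, per row.
## mi, mj: row means; vi, vj: row variances; ni, nj: group sizes.
welch_onesided_log10p <- function(mi, mj, vi, vj, ni, nj) {
  se2 <- vi / ni + vj / nj
  df <- se2^2 / ((vi / ni)^2 / (ni - 1) + (vj / nj)^2 / (nj - 1))
  t <- (mi - mj) / sqrt(se2)
  log10p <- stats::pt(t, df, lower.tail = FALSE, log.p = TRUE) / log(10)
  ## zero-variance limits of the t statistic
  zero <- se2 == 0
  if (any(zero)) {
    log10p[zero & mi > mj] <- -Inf
    log10p[zero & mi == mj] <- log10(0.5)
    log10p[zero & mi < mj] <- 0
  }
  log10p
}

#' Step 2: pairwise one-sided t-tests and the association rule
#'
#' For every window surviving the ANOVA filter and every ordered group
#' pair (i, j), tests H0: mu_i <= mu_j with a one-sided Welch two-sample
#' t-test.  A window is an associated window of group i when the null is
#' rejected (raw p < `alpha2`) against more than `m` of the other
#' groups (strictly greater by default; see [epom_thresholds()]).
#'
#' @param sm a `"signal_matrix"` already restricted to post-ANOVA
#'   windows, or a full matrix together with `kept`.
#' @param thresholds an `"epom_thresholds"`.
#' @param kept optional logical vector selecting the post-ANOVA windows
#'   of `sm`.
#' @return named list (one element per group) of character window ids.
#' @export
pairwise_ttest <- function(sm, thresholds = epom_thresholds(),
                           kept = NULL) {
  stopifnot(inherits(sm, "signal_matrix"),
            inherits(thresholds, "epom_thresholds"))
  values <- sm$values
  windows <- sm$windows
  if (!is.null(kept)) {
    values <- values[kept, , drop = FALSE]
    windows <- windows[kept, , drop = FALSE]
  }
  groups <- droplevels(matrix_groups(sm))
  labels <- levels(groups)
  G <- length(labels)
  if (thresholds$m >= G) stop("m must be smaller than the number of groups")
  ids <- window_id(windows)
  W <- nrow(values)
  if (W == 0) {
    return(stats::setNames(rep(list(character(0)), G), labels))
  }
  ## per-group row means and variances
  means <- vars <- matrix(0, W, G, dimnames = list(NULL, labels))
  ng <- integer(G)
  for (g in seq_len(G)) {
    cols <- which(groups == labels[g])
    ng[g] <- length(cols)
    sub <- values[, cols, drop = FALSE]
    means[, g] <- rowMeans(sub)
    vars[, g] <- rowSums((sub - means[, g])^2) / (ng[g] - 1)
  }
  n_pairs <- G * (G - 1)
  log10_alpha2 <- log10(thresholds$alpha2) -
    if (thresholds$step2_bonferroni) log10(n_pairs) else 0
  rejections <- matrix(0L, W, G, dimnames = list(NULL, labels))
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (i == j) next
      lp <- welch_onesided_log10p(means[, i], means[, j],
                                  vars[, i], vars[, j], ng[i], ng[j])
      rejections[, i] <- rejections[, i] + (lp < log10_alpha2)
    }
  }
  assoc <- if (thresholds$m_rule == "greater") {
    rejections > thresholds$m
  } else {
    rejections >= thresholds$m
  }
  out <- lapply(seq_len(G), function(g) ids[assoc[, g]])
  stats::setNames(out, labels)
}

#' Run steps 1 and 2 on one signal matrix
#'
#' Convenience wrapper: ANOVA filter then pairwise t-tests, returning an
#' `"epom_assoc"` object carrying the per-group associated window sets
#' and stage counts.
#'
#' @inheritParams anova_filter
#' @return object of class `"epom_assoc"`: list with `marks`,
#'   `region_class`, `sets` (named list of window-id vectors per group),
#'   `counts` (data frame of stage counts), `thresholds`,
#'   `combine_mode`, `n_candidates`, `n_post_anova`.
#' @export
associate_windows <- function(sm, thresholds = epom_thresholds()) {
  flt <- anova_filter(sm, thresholds)
  sets <- pairwise_ttest(sm, thresholds, kept = flt$kept)
  epom_assoc(sets,
             marks = sm$mark %||% NA_character_,
             region_class = sm$region_class,
             thresholds = thresholds,
             combine_mode = "single",
             n_candidates = flt$n_tested,
             n_post_anova = sum(flt$kept))
}

epom_assoc <- function(sets, marks, region_class, thresholds,
                       combine_mode, n_candidates, n_post_anova) {
  counts <- data.frame(group = names(sets),
                       n_associated = vapply(sets, length, 1L),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(marks = marks, region_class = region_class,
                 sets = sets, counts = counts, thresholds = thresholds,
                 combine_mode = combine_mode,
                 n_candidates = n_candidates,
                 n_post_anova = n_post_anova),
            class = "epom_assoc")
}

#' @export
print.epom_assoc <- function(x, ...) {
  cat("epom_assoc (", paste(x$marks, collapse = "+"), ", ",
      x$region_class %||% "?", ", ", x$combine_mode, ")\n", sep = "")
  cat("  candidates:", x$n_candidates, " post-ANOVA:",
      paste(x$n_post_anova, collapse = "/"), "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Combine associated windows across histone marks
#'
#' Per group, takes the set union (default) or intersection of the
#' associated windows identified separately for each mark.
#'
#' @param results list of `"epom_assoc"` objects over the same groups
#'   and region class.
#' @param mode `"union"` or `"intersection"`.
#' @return a combined `"epom_assoc"`.
#' @export
combine_marks <- function(results, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "epom_assoc")))
  groups <- names(results[[1]]$sets)
  for (r in results[-1]) {
    if (!setequal(names(r$sets), groups)) {
      stop("results have mismatched group sets")
    }
  }
  combine2 <- if (mode == "union") union else intersect
  sets <- stats::setNames(lapply(groups, function(g) {
    Reduce(combine2, lapply(results, function(r) r$sets[[g]]))
  }), groups)
  epom_assoc(sets,
             marks = unlist(lapply(results, function(r) r$marks)),
             region_class = results[[1]]$region_class,
             thresholds = results[[1]]$thresholds,
             combine_mode = mode,
             n_candidates = results[[1]]$n_candidates,
             n_post_anova = vapply(results, function(r) r$n_post_anova, 1L))
}

#' Rank histone marks by their number of differential windows
#'
#' Orders marks by how many candidate windows pass the ANOVA filter at
#' `alpha1` (Bonferroni-corrected), a proxy for how informative each
#' mark is about group differences.  Ties break alphabetically.
#'
#' @param matrices list of `"signal_matrix"` objects, one per mark,
#'   sharing windows and design.
#' @param alpha1 step-1 threshold (default 1e-10).
#' @return data frame with columns `mark` and `n_differential`, in
#'   descending count order.
#' @export
rank_marks_by_differential_regions <- function(matrices, alpha1 = 1e-10) {
  th <- epom_thresholds(alpha1 = alpha1)
  counts <- vapply(matrices, function(sm) sum(anova_filter(sm, th)$kept), 1L)
  marks <- vapply(matrices, function(sm) sm$mark %||% NA_character_, "")
  ord <- order(-counts, marks)
  data.frame(mark = marks[ord], n_differential = counts[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of associated among candidate regions
#'
#' The reporting convention for stage-count tables: per group,
#' `100 * associated / candidates` rounded to 2 decimals.
#'
#' @param n_associated integer vector of associated-region counts.
#' @param n_candidates candidate-region count (scalar or vector).
#' @return numeric vector of percentages rounded to 2 decimals.
#' @export
association_percentage <- function(n_associated, n_candidates) {
  round(100 * n_associated / n_candidates, 2)
}

#' Stage-count report for an association result
#'
#' @param assoc an `"epom_assoc"`.
#' @param n_candidates candidate count used as the percentage
#'   denominator (defaults to the one recorded in `assoc`).
#' @return data frame with columns `group`, `n_associated`,
#'   `pct_of_candidates`.
#' @export
stage_report <- function(assoc, n_candidates = assoc$n_candidates) {
  df <- assoc$counts
  df$pct_of_candidates <- association_percentage(df$n_associated,
                                                 n_candidates)
  df
}
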