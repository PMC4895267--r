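# The top-level fit: run the three-step testing procedure on one or
# more per-mark signal matrices and return a classed result.

#' Fit the Epigenome Overlap Measure
#'
#' Runs the full three-step testing procedure on region x sample signal
#' matrices for one region class (candidate enhancers or promoters):
#'
#' 1. **ANOVA filter** — per window, a one-way ANOVA across groups;
#'    windows with Bonferroni-corrected p below `alpha1` survive.
#' 2. **Pairwise t-tests** — per surviving window and ordered group pair
#'    (i, j), a one-sided Welch t-test of whether group i's mean signal
#'    exceeds group j's; a window is *associated* with group i when the
#'    test rejects (raw p < `alpha2`) against more than `m` other
#'    groups.  With several marks, per-group sets are combined across
#'    marks by union (default) or intersection.
#' 3. **Overlap test** — for every group pair, the exact overlap test of
#'    their associated sets against the population formed by the union
#'    over all groups; the EPOM score is `-log10` of the Bonferroni-
#'    corrected p-value.
#'
#' @param matrices a `"signal_matrix"` or a list of them (one per
#'   histone mark, same windows/design/region class).
#' @param alpha1,alpha2,m,m_rule,step2_bonferroni testing thresholds;
#'   see [epom_thresholds()].
#' @param thresholds an `"epom_thresholds"` object overriding the
#'   individual arguments.
#' @param combine `"union"` or `"intersection"` across marks.
#' @param bonferroni_factor override for the pairwise overlap-test
#'   Bonferroni factor (default G(G-1)/2).
#' @return object of class `"epom"`: list with `assoc` (the combined
#'   `"epom_assoc"`), `per_mark` (per-mark `"epom_assoc"` list),
#'   `matrix` (the `"epom_matrix"`), `thresholds`, `combine`, `call`.
#' @seealso [associate_windows()], [epom_matrix()], [saturate()]
#' @examples
#' sim <- simulate_dataset(sim_config(n_groups = 3, samples_per_group = 3,
#'                                    n_windows = 300, seed = 1))
#' fit <- epom(sim$matrices, alpha1 = 1e-4, m = 1)
#' fit
#' @export
epom <- function(matrices, alpha1 = 1e-10, alpha2 = 0.01, m = 14,
                 m_rule = "greater", step2_bonferroni = FALSE,
                 thresholds = NULL,
                 combine = c("union", "intersection"),
                 bonferroni_factor = NULL) {
  combine <- match.arg(combine)
  if (inherits(matrices, "signal_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "signal_matrix")))
  th <- thresholds %||% epom_thresholds(alpha1 = alpha1, alpha2 = alpha2,
                                        m = m, m_rule = m_rule,
                                        step2_bonferroni = step2_bonferroni)
  per_mark <- lapply(matrices, associate_windows, thresholds = th)
  assoc <- if (length(per_mark) == 1) {
    per_mark[[1]]
  } else {
    combine_marks(per_mark, mode = combine)
  }
  mat <- epom_matrix(assoc, bonferroni_factor = bonferroni_factor)
  structure(list(assoc = assoc, per_mark = per_mark, matrix = mat,
                 thresholds = th, combine = combine,
                 call = match.call()),
            class = "epom")
}

#' @export
print.epom <- function(x, ...) {
  th <- x$thresholds
  cat("EPOM fit (", length(x$per_mark), " mark(s), combine = ",
      x$combine, ")\n", sep = "")
  cat(sprintf("  thresholds: alpha1 = %g, alpha2 = %g, m = %d (%s)\n",
              th$alpha1, th$alpha2, th$m, th$m_rule))
  cat("  candidates:", x$assoc$n_candidates,
      " population:", x$matrix$n, "\n")
  print(x$matrix)
  invisible(x)
}

#' @export
summary.epom <- function(object, ...) {
  rep <- stage_report(object$assoc)
  sc <- object$matrix$scores
  diag(sc) <- NA
  structure(list(report = rep,
                 thresholds = object$thresholds,
                 n_population = object$matrix$n,
                 top_pairs = top_pairs(object$matrix, 5)),
            class = "summary.epom")
}

#' @export
print.summary.epom <- function(x, ...) {
  cat("Associated regions per group:\n")
  print(x$report, row.names = FALSE)
  cat("\nPopulation (union of associated sets):", x$n_population, "\n")
  cat("Top off-diagonal EPOM scores:\n")
  print(x$top_pairs, row.names = FALSE)
  invisible(x)
}

top_pairs <- function(mat, k = 5) {
  sc <- mat$scores
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  ord <- order(-sc[ut])
  ut <- ut[head(ord, k), , drop = FALSE]
  data.frame(group_i = mat$groups[ut[, 1]],
             group_j = mat$groups[ut[, 2]],
             score = sc[ut],
             stringsAsFactors = FALSE)
}

#' @export
coef.epom <- function(object, ...) object$matrix$scores

#' @export
as.matrix.epom <- function(x, ...) x$matrix$scores

#' Heatmap of an EPOM score matrix
#'
#' Draws the correspondence map as a base-graphics heatmap, saturated
#' at `cap` (scores above the cap are shown at the cap).
#'
#' @param x an `"epom"` fit or an `"epom_matrix"`.
#' @param cap saturation level (default 20); `Inf` disables saturation.
#' @param col colour ramp.
#' @param ... passed to [graphics::image()].
#' @export
plot.epom <- function(x, cap = 20, ...) {
  plot(x$matrix, cap = cap, ...)
}

#' @rdname plot.epom
#' @export
plot.epom_matrix <- function(x, cap = 20,
                             col = grDevices::hcl.colors(64, "YlOrRd",
                                                         rev = TRUE),
                             ...) {
  m <- if (is.finite(cap)) saturate(x, cap)$scores else x$scores
  G <- ncol(m)
  graphics::image(seq_len(G), seq_len(G), t(m[G:1, , drop = FALSE]),
                  col = col, axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, max(m, 1)), ...)
  graphics::axis(1, at = seq_len(G), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(G), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

#' Export the associated regions of a fit as per-group BED files
#'
#' Writes one BED3 file per group, named `<class>_<group>.bed`, plus a
#' stage-count TSV report.
#'
#' @param fit an `"epom"` fit.
#' @param dir output directory (created if needed).
#' @param header optional provenance comment lines for the BED files.
#' @return invisibly, the vector of paths written.
#' @export
export_associated_regions <- function(fit, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- fit$assoc$region_class %||% "regions"
  paths <- character(0)
  for (g in names(fit$assoc$sets)) {
    ids <- fit$assoc$sets[[g]]
    w <- if (length(ids)) sort_windows(parse_window_id(ids)) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0))
    p <- file.path(dir, paste0(cls, "_", gsub("[^A-Za-z0-9._-]", "_", g),
                               ".bed"))
    write_regions(w, p, header = header)
    paths <- c(paths, p)
  }
  rp <- file.path(dir, paste0(cls, "_stage_counts.tsv"))
  utils::write.table(stage_report(fit$assoc), rp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, rp))
}
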