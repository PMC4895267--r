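# Step 3: the exact overlap test and the EPOM score.
#
# The test models two region sets A and B as samples drawn without
# replacement from a finite population of n regions; the statistic is
# |A n B| and the p-value is the exact upper tail
#
#   p = sum_{i = |AnB|}^{min(|A|,|B|)}
#         C(n,i) C(n-i, |A|-i) C(n-|A|, |B|-i) / ( C(n,|A|) C(n,|B|) )
#
# which equals the hypergeometric upper tail P(X >= |AnB|).  On real
# data these p-values underflow double precision by hundreds of orders
# of magnitude, so everything is evaluated in log space via lgamma with
# log-sum-exp accumulation; raw binomials are never multiplied.

lchoose_ <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

#' Exact overlap-test p-value in log10 space
#'
#' @param n population size (number of regions in the universe).
#' @param size_a,size_b sizes of the two region sets.
#' @param overlap observed size of their intersection.
#' @return `log10(p)` of the upper-tail overlap test (a value <= 0).
#' @examples
#' overlap_log_pvalue(2, 1, 1, 1)  # log10(0.5)
#' @export
overlap_log_pvalue <- function(n, size_a, size_b, overlap) {
  stopifnot(length(n) == 1, n >= 1,
            size_a >= 0, size_b >= 0, size_a <= n, size_b <= n,
            overlap >= 0)
  if (overlap > min(size_a, size_b)) {
    stop("overlap exceeds min(|A|, |B|)")
  }
  if (overlap < size_a + size_b - n) {
    stop("overlap below the feasible minimum |A|+|B|-n")
  }
  i <- overlap:min(size_a, size_b)
  log_terms <- lchoose_(n, i) + lchoose_(n - i, size_a - i) +
    lchoose_(n - size_a, size_b - i) -
    lchoose_(n, size_a) - lchoose_(n, size_b)
  lp <- logsumexp(log_terms) / log(10)
  min(lp, 0)  # clamp rounding drift above exactly-1 tails
}

#' EPOM score from a log10 p-value
#'
#' The score is `-log10` of the Bonferroni-corrected p-value, computed
#' in log space: `max(0, -log10(p) - log10(num_tests))`, with the
#' corrected p clamped at 1.
#'
#' @param log10_p log10 p-value (<= 0), e.g. from
#'   [overlap_log_pvalue()].
#' @param num_tests Bonferroni factor (>= 1).
#' @return non-negative EPOM score.
#' @export
epom_score <- function(log10_p, num_tests = 1) {
  if (any(num_tests < 1)) stop("num_tests must be >= 1")
  if (any(log10_p > 0)) stop("log10_p must be <= 0")
  pmax(0, -log10_p - log10(num_tests))
}

#' Pairwise EPOM score matrix from associated region sets
#'
#' The population is the union of all groups' associated windows.  For
#' each unordered pair of groups the overlap test compares their sets
#' against this population; off-diagonal p-values are Bonferroni-
#' corrected by the number of unordered pairs G(G-1)/2.  Diagonal
#' entries score each set's full self-overlap and are not counted as
#' hypothesis tests (no correction).  Groups with empty sets score 0
#' against everything (with a warning), matching near-empty groups in
#' real stage-count tables.
#'
#' @param assoc an `"epom_assoc"` (see [associate_windows()]), or a
#'   named list of character region-id vectors.
#' @param bonferroni_factor override for the off-diagonal Bonferroni
#'   factor (default `G*(G-1)/2`).
#' @return object of class `"epom_matrix"`: list with `groups`,
#'   `scores` and `log10p` (G x G symmetric matrices), `n`
#'   (population size), `bonferroni_factor`, `region_class`.
#' @export
epom_matrix <- function(assoc, bonferroni_factor = NULL) {
  sets <- if (inherits(assoc, "epom_assoc")) assoc$sets else assoc
  stopifnot(is.list(sets), !is.null(names(sets)))
  groups <- names(sets)
  G <- length(groups)
  if (G < 2) stop("need at least 2 groups")
  empty <- vapply(sets, length, 1L) == 0
  if (any(empty)) {
    warning("group(s) with no associated regions score 0: ",
            paste(groups[empty], collapse = ", "))
  }
  population <- unique(unlist(sets, use.names = FALSE))
  n <- length(population)
  bf <- bonferroni_factor %||% (G * (G - 1) / 2)
  scores <- log10p <- matrix(0, G, G, dimnames = list(groups, groups))
  for (i in seq_len(G)) {
    for (j in i:G) {
      if (empty[i] || empty[j]) next
      a <- length(sets[[i]])
      b <- length(sets[[j]])
      k <- if (i == j) a else length(intersect(sets[[i]], sets[[j]]))
      lp <- overlap_log_pvalue(n, a, b, k)
      sc <- epom_score(lp, if (i == j) 1 else bf)
      log10p[i, j] <- log10p[j, i] <- lp
      scores[i, j] <- scores[j, i] <- sc
    }
  }
  structure(list(groups = groups, scores = scores, log10p = log10p,
                 n = n, bonferroni_factor = bf,
                 region_class = if (inherits(assoc, "epom_assoc"))
                   assoc$region_class else NULL),
            class = "epom_matrix")
}

#' Saturate an EPOM matrix for display
#'
#' Caps scores at `cap` (default 20), the convention used when plotting
#' correspondence maps; the input object is not modified.
#'
#' @param x an `"epom_matrix"` or a numeric matrix.
#' @param cap saturation level (> 0).
#' @return same type as `x`, with `scores` entries `min(score, cap)`.
#' @export
saturate <- function(x, cap = 20) {
  stopifnot(cap > 0)
  if (inherits(x, "epom_matrix")) {
    x$scores <- pmin(x$scores, cap)
    x$saturated_at <- cap
    return(x)
  }
  pmin(x, cap)
}

#' @export
print.epom_matrix <- function(x, digits = 2, ...) {
  cat("EPOM score matrix:", length(x$groups), "groups, population of",
      x$n, "regions (Bonferroni factor", x$bonferroni_factor, ")\n")
  print(round(x$scores, digits))
  invisible(x)
}

#' @export
as.matrix.epom_matrix <- function(x, ...) x$scores

#' Write an EPOM matrix as TSV
#'
#' Groups appear as the header row and first column.
#'
#' @param x an `"epom_matrix"`.
#' @param path output path.
#' @param what `"scores"` or `"log10p"`.
#' @export
write_epom_matrix <- function(x, path, what = c("scores", "log10p")) {
  what <- match.arg(what)
  m <- x[[what]]
  df <- data.frame(group = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
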