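# Steps 1-2: ANOVA filter, pairwise one-sided Welch t-tests, mark
# combination and mark ranking.

test_that("row-wise ANOVA matches the reference one-way ANOVA", {
  set.seed(42)
  d <- toy_design(G = 5, n = 4)
  values <- matrix(rlnorm(30 * 20, 1, 0.5), nrow = 30)
  sm <- toy_matrix(values, d)
  flt <- anova_filter(sm, epom_thresholds(alpha1 = 0.05))
  groups <- factor(d$group)
  for (k in c(1, 7, 30)) {
    ref <- stats::oneway.test(sm$values[k, ] ~ groups, var.equal = TRUE)
    expect_equal(flt$log10p[k], log10(ref$p.value), tolerance = 1e-10)
    expect_equal(flt$log10p_adj[k],
                 min(0, flt$log10p[k] + log10(nrow(values))))
  }
})

test_that("degenerate windows follow the F-statistic limits", {
  d <- toy_design(G = 3, n = 3)
  vals <- rbind(rep(2, 9),                      # no variance at all
                c(rep(10, 3), rep(0, 6)),       # between, no within
                rlnorm(9))
  sm <- toy_matrix(vals, d)
  flt <- anova_filter(sm, epom_thresholds(alpha1 = 1e-4))
  expect_equal(flt$log10p_adj[1], 0)       # p = 1: filtered out
  expect_equal(flt$log10p_adj[2], -Inf)    # p -> 0: kept
  expect_true(flt$kept[2])
  expect_false(flt$kept[1])
})

test_that("pairwise tests match the reference Welch t-test", {
  set.seed(7)
  d <- toy_design(G = 3, n = 5)
  values <- matrix(rlnorm(20 * 15), nrow = 20)
  sm <- toy_matrix(values, d)
  groups <- factor(d$group)
  for (k in c(3, 11)) {
    for (i in levels(groups)) {
      for (j in setdiff(levels(groups), i)) {
        ref <- stats::t.test(sm$values[k, groups == i],
                             sm$values[k, groups == j],
                             alternative = "greater")
        got <- epom:::welch_onesided_log10p(
          mean(sm$values[k, groups == i]), mean(sm$values[k, groups == j]),
          var(sm$values[k, groups == i]), var(sm$values[k, groups == j]),
          5, 5)
        expect_equal(got, log10(ref$p.value), tolerance = 1e-10)
      }
    }
  }
})

test_that("identical groups never reject (t = 0, one-sided p = 0.5)", {
  d <- toy_design(G = 2, n = 4)
  sm <- toy_matrix(matrix(5, 2, 8), d)
  sets <- pairwise_ttest(sm, epom_thresholds(alpha2 = 0.01, m = 0,
                                             m_rule = "greater"))
  expect_equal(vapply(sets, length, 1L), c(g1 = 0L, g2 = 0L))
})

test_that("planted dominant group is the only one associated", {
  set.seed(19)
  G <- 4
  d <- toy_design(G = G, n = 6)
  values <- matrix(rnorm(50 * 24, 2, 1), nrow = 50)
  planted <- 1:10
  values[planted, d$group == "g1"] <- values[planted, d$group == "g1"] + 10
  values <- pmax(values, 0)
  sm <- toy_matrix(values, d)
  th <- epom_thresholds(alpha1 = 1e-4, alpha2 = 0.01, m = G - 2)
  res <- associate_windows(sm, th)
  ids <- epom:::window_id(sm$windows[planted, ])
  expect_setequal(res$sets$g1, ids)
  expect_equal(sum(lengths(res$sets[-1])), 0)
})

test_that("rejections for (i,j) and (j,i) are mutually exclusive", {
  set.seed(23)
  for (rep in 1:20) {
    xi <- rnorm(4); xj <- rnorm(4)
    pi_ <- epom:::welch_onesided_log10p(mean(xi), mean(xj), var(xi),
                                        var(xj), 4, 4)
    pj_ <- epom:::welch_onesided_log10p(mean(xj), mean(xi), var(xj),
                                        var(xi), 4, 4)
    # one-sided p-values in the two directions sum to 1
    expect_equal(10^pi_ + 10^pj_, 1, tolerance = 1e-10)
    expect_false(pi_ < log10(0.4) && pj_ < log10(0.4))
  }
})

test_that("association sets grow when m drops or alpha2 rises", {
  set.seed(31)
  d <- toy_design(G = 4, n = 4)
  values <- pmax(matrix(rnorm(200 * 16, 2, 1), nrow = 200), 0)
  values[1:30, d$group == "g2"] <- values[1:30, d$group == "g2"] + 3
  sm <- toy_matrix(values, d)
  grid_m <- 0:3
  sets_by_m <- lapply(grid_m, function(m)
    pairwise_ttest(sm, epom_thresholds(alpha2 = 0.05, m = m)))
  for (i in seq_along(grid_m)[-1]) {
    for (g in names(sets_by_m[[1]])) {
      expect_true(all(sets_by_m[[i]][[g]] %in% sets_by_m[[i - 1]][[g]]))
    }
  }
  lo <- pairwise_ttest(sm, epom_thresholds(alpha2 = 0.005, m = 2))
  hi <- pairwise_ttest(sm, epom_thresholds(alpha2 = 0.1, m = 2))
  for (g in names(lo)) expect_true(all(lo[[g]] %in% hi[[g]]))
})

test_that("marks combine by union or intersection per group", {
  mk <- function(sets, mark) {
    epom:::epom_assoc(sets, marks = mark, region_class = "enhancer",
                      thresholds = epom_thresholds(), combine_mode = "single",
                      n_candidates = 10L, n_post_anova = 5L)
  }
  a <- mk(list(g1 = c("chr1:0-200", "chr1:200-400"), g2 = "chr1:400-600"),
          "H3K4me1")
  b <- mk(list(g1 = "chr1:200-400", g2 = character(0)), "H3K27ac")
  u <- combine_marks(list(a, b), "union")
  expect_setequal(u$sets$g1, c("chr1:0-200", "chr1:200-400"))
  expect_setequal(u$sets$g2, "chr1:400-600")
  i <- combine_marks(list(a, b), "intersection")
  expect_equal(i$sets$g1, "chr1:200-400")
  expect_length(i$sets$g2, 0)
  ## idempotence: identical inputs give union = intersection
  expect_equal(combine_marks(list(a, a), "union")$sets,
               combine_marks(list(a, a), "intersection")$sets)
  bad <- mk(list(g1 = character(0), g3 = character(0)), "H3K4me3")
  expect_error(combine_marks(list(a, bad)), "mismatched")
})

test_that("marks rank by their differential-window counts", {
  set.seed(47)
  d <- toy_design(G = 3, n = 4)
  base <- pmax(matrix(rnorm(100 * 12, 2, 1), nrow = 100), 0)
  strong <- base
  strong[1:40, d$group == "g1"] <- strong[1:40, d$group == "g1"] + 10
  smA <- toy_matrix(strong, d, mark = "markA")
  smB <- toy_matrix(base, d, mark = "markB")
  rk <- rank_marks_by_differential_regions(list(smB, smA), alpha1 = 1e-3)
  expect_equal(rk$mark[1], "markA")
  expect_gte(rk$n_differential[1], rk$n_differential[2])
  ## identical tracks tie and order alphabetically
  rk2 <- rank_marks_by_differential_regions(
    list(toy_matrix(base, d, mark = "zeta"),
         toy_matrix(base, d, mark = "alpha")), alpha1 = 1e-3)
  expect_equal(rk2$mark, c("alpha", "zeta"))
  expect_equal(rk2$n_differential[1], rk2$n_differential[2])
  ## single mark
  expect_equal(nrow(rank_marks_by_differential_regions(list(smA))), 1)
})

test_that("association percentages follow the reporting convention", {
  expect_equal(association_percentage(c(51666, 11942),
                                      c(4056578, 1401636)),
               c(1.27, 0.85))
  d <- toy_design(G = 2, n = 2)
  sm <- toy_matrix(pmax(matrix(rnorm(10 * 4, 2, 1), 10), 0), d)
  rep <- stage_report(associate_windows(sm, epom_thresholds(alpha1 = 0.5,
                                                            m = 0)))
  expect_named(rep, c("group", "n_associated", "pct_of_candidates"))
  expect_equal(rep$pct_of_candidates,
               round(100 * rep$n_associated / 10, 2))
})
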