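# Region merging, target-gene assignment, gene-set/SNP enrichment and
# specificity summaries.

test_that("book-ended windows merge; gapped windows do not", {
  w <- data.frame(chrom = "chr1", start = c(0L, 200L, 400L, 800L),
                  end = c(200L, 400L, 600L, 1000L))
  m <- merge_adjacent(w)
  expect_equal(m$start, c(0L, 800L))
  expect_equal(m$end, c(600L, 1000L))
  ## k consecutive windows collapse to one region of length 200k
  k <- 7
  run <- toy_windows(k)
  expect_equal(merge_adjacent(run),
               data.frame(chrom = "chr1", start = 0L, end = 200L * k))
})

test_that("merging is idempotent and conserves covered bp", {
  set.seed(77)
  for (rep in 1:10) {
    starts <- sort(sample(seq(0, 20000, by = 200), 30))
    w <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                    start = starts, end = starts + 200L)
    w <- unique(w)
    m <- merge_adjacent(w)
    expect_equal(sum(m$end - m$start), sum(w$end - w$start))
    expect_equal(merge_adjacent(m), m)
    expect_lte(nrow(m), nrow(w))
  }
})

toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    tss = c(250000L, 90000L, 400000L),
    strand = c("+", "-", "-"),
    stringsAsFactors = FALSE))
}

test_that("enhancers take the nearest TSS in either direction", {
  ann <- toy_annotation()
  region <- data.frame(chrom = "chr1", start = 99900L, end = 100100L)
  a <- assign_target_genes(region, ann, "enhancer")
  expect_equal(a$gene_id, "gB")               # 10 kb away beats 150 kb
  expect_equal(a$distance, 90000 - 100000)
  far <- data.frame(chrom = "chr1", start = 699900L, end = 700100L)
  expect_true(is.na(assign_target_genes(far, ann, "enhancer")$gene_id))
})

test_that("promoters only take genes transcribed away from the region", {
  ann <- toy_annotation()
  ## region just upstream of the '+' gene gA at 250 kb: gA qualifies and
  ## is nearer than the '-' gene gB at 90 kb
  up <- data.frame(chrom = "chr1", start = 240000L, end = 240200L)
  a <- assign_target_genes(up, ann, "promoter")
  expect_equal(a$gene_id, "gA")
  ## region 1 kb downstream of gA's TSS: '+' TSS < midpoint, so gA is
  ## excluded; '-' gB lies left (gB qualifies: tss <= mid), distance 161 kb
  down <- data.frame(chrom = "chr1", start = 251000L, end = 251200L)
  b <- assign_target_genes(down, ann, "promoter")
  expect_false(identical(b$gene_id, "gA"))
  expect_equal(b$gene_id, "gB")
  ## beyond 200 kb nothing qualifies
  c_ <- assign_target_genes(down, ann, "promoter", max_distance = 100000)
  expect_true(is.na(c_$gene_id))
})

test_that("enhancer assignment is at least as permissive as promoter", {
  set.seed(88)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
    tss = sort(sample(0:500000, 20)),
    strand = sample(c("+", "-"), 20, TRUE), stringsAsFactors = FALSE))
  starts <- sample(seq(0, 500000, by = 200), 40)
  regions <- data.frame(chrom = "chr1", start = starts,
                        end = starts + 200L)
  e <- assign_target_genes(regions, ann, "enhancer")
  p <- assign_target_genes(regions, ann, "promoter")
  ## whatever the promoter rule assigns, the enhancer rule also assigns,
  ## and never to a more distant TSS
  assigned <- !is.na(p$gene_id)
  expect_true(all(!is.na(e$gene_id[assigned])))
  expect_true(all(abs(e$distance[assigned]) <= abs(p$distance[assigned])))
})

test_that("equidistant ties resolve to the smallest gene id", {
  ann <- gene_annotation(data.frame(
    gene_id = c("zz", "aa"), chrom = "chr1", tss = c(9000L, 11000L),
    strand = c("+", "+"), stringsAsFactors = FALSE))
  region <- data.frame(chrom = "chr1", start = 9900L, end = 10100L)
  expect_equal(assign_target_genes(region, ann, "enhancer")$gene_id, "aa")
})

test_that("gene sharing histograms count groups per gene", {
  assignments <- list(
    g1 = c("a", "b", "c"),
    g2 = c("b", "c", "d"),
    g3 = c("c"))
  out <- count_gene_sharing(assignments, breaks = c(1, 2, Inf))
  expect_equal(out$group, c("g1", "g2", "g3"))
  ## gene a: 1 group; b: 2; c: 3; d: 1
  expect_equal(out[["n=1"]], c(1L, 1L, 0L))
  expect_equal(out[["n=2"]], c(1L, 1L, 0L))
  expect_equal(out[["n>2"]], c(1L, 1L, 1L))
  ## identical gene lists give identical histograms
  two <- count_gene_sharing(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(unlist(two[1, -1]), unlist(two[2, -1]))
})

test_that("gene-set enrichment reuses the overlap-test engine exactly", {
  sets <- list(g1 = sprintf("G%02d", 1:30), g2 = sprintf("G%02d", 21:50))
  coll <- structure(list(
    T1 = list(name = "t1", genes = sprintf("G%02d", 1:15)),
    T2 = list(name = "t2", genes = sprintf("G%02d", 60:70))),
    class = "gene_set_collection")
  enr <- gene_set_enrichment(sets, coll)
  pop <- union(sets$g1, sets$g2)  # 50 genes
  row <- enr[enr$group == "g1" & enr$term == "T1", ]
  expect_equal(row$log10_p,
               overlap_log_pvalue(length(pop), 30, 15, 15))
  expect_equal(row$score, epom_score(row$log10_p, 2))
  ## term disjoint from the population scores 0
  row2 <- enr[enr$group == "g1" & enr$term == "T2", ]
  expect_equal(row2$score, 0)
  expect_error(gene_set_enrichment(list(g1 = character(0)), coll,
                                   population = character(0)), "empty")
})

test_that("planted term tops its group and scores 0 elsewhere", {
  set.seed(31)
  sim <- simulate_dataset(sim_config(n_groups = 3, samples_per_group = 5,
                                     n_windows = 2000, seed = 31))
  fit <- epom(sim$matrices, alpha1 = 1e-3, m = 1)
  tg <- target_genes(fit, sim$annotation, merge = FALSE)
  enr <- gene_set_enrichment(tg, sim$gene_sets)
  top1 <- top_terms(enr, 1)
  expect_equal(top1$term[top1$group == "group01"], "TERM_group01")
  expect_equal(top1$term[top1$group == "group02"], "TERM_group02")
  other <- enr[enr$group == "group03" & enr$term == "TERM_group01", ]
  expect_equal(other$score, 0)
})

test_that("specificity proportions match a direct counting oracle", {
  mk_row <- function(g, term, p) {
    data.frame(group = g, term = term, term_name = term, overlap = 1,
               size_a = 1, size_b = 1, population = 10,
               log10_p = log10(p), score = -log10(p),
               stringsAsFactors = FALSE)
  }
  enr <- rbind(mk_row("g1", "T1", 1e-5), mk_row("g1", "T2", 1e-4),
               mk_row("g2", "T2", 1e-6), mk_row("g2", "T3", 0.5),
               mk_row("g3", "T4", 0.2))
  out <- specificity_summary(enr, p_threshold = 1e-3)
  ## enriched: g1 {T1, T2}, g2 {T2}, g3 {}; T2 shared by two groups
  expect_equal(out$n_enriched, c(2L, 1L, 0L))
  expect_equal(out$proportion_specific, c(0.5, 0, 0))
  ## all terms unique -> proportion 1; all shared -> proportion 0
  uniq <- rbind(mk_row("g1", "T1", 1e-5), mk_row("g2", "T2", 1e-5))
  expect_equal(specificity_summary(uniq)$proportion_specific, c(1, 1))
  shared <- rbind(mk_row("g1", "T1", 1e-5), mk_row("g2", "T1", 1e-5))
  expect_equal(specificity_summary(shared)$proportion_specific, c(0, 0))
  expect_error(specificity_summary(mk_row("g1", "T1", 1e-5)), ">= 2")
})

test_that("SNP enrichment finds the planted group and respects half-open
           window membership", {
  bg <- toy_windows(100)
  sets <- list(g1 = epom:::window_id(bg[1:10, ]),
               g2 = epom:::window_id(bg[51:60, ]))
  assoc <- epom:::epom_assoc(sets, marks = "H3K4me1",
                             region_class = "enhancer",
                             thresholds = epom_thresholds(),
                             combine_mode = "single",
                             n_candidates = 100L, n_post_anova = 20L)
  ## SNPs only inside g1's windows; boundary SNP at pos 2000 belongs to
  ## the *next* window (half-open), outside g1
  snps <- structure(data.frame(
    chrom = "chr1", pos = c(seq(50, 1850, by = 200), 2000L),
    snp_id = sprintf("rs%d", 1:11), term = "traitA",
    stringsAsFactors = FALSE), class = c("snp_catalog", "data.frame"))
  enr <- snp_enrichment(assoc, snps, bg)
  expect_gt(enr$score[enr$group == "g1"], enr$score[enr$group == "g2"])
  expect_equal(enr$size_b[1], 11L)  # 10 in g1 + the boundary window
  expect_equal(enr$overlap[enr$group == "g1"], 10L)
  ## SNPs off the background chromosome are skipped with a message
  snps2 <- snps
  snps2$chrom[1] <- "chrX"
  expect_message(snp_enrichment(assoc, snps2, bg), "skipping")
  ## no SNP in any background window: all scores 0
  none <- snps
  none$pos <- none$pos + 1000000L
  enr0 <- snp_enrichment(assoc, none, bg)
  expect_equal(enr0$score, rep(0, 2))
})

test_that("per-term SNP mode Bonferroni-corrects over terms", {
  bg <- toy_windows(50)
  sets <- list(g1 = epom:::window_id(bg[1:5, ]),
               g2 = epom:::window_id(bg[21:25, ]))
  assoc <- epom:::epom_assoc(sets, marks = "m", region_class = "enhancer",
                             thresholds = epom_thresholds(),
                             combine_mode = "single",
                             n_candidates = 50L, n_post_anova = 10L)
  snps <- structure(data.frame(
    chrom = "chr1", pos = c(100L, 300L, 4100L),
    snp_id = c("rs1", "rs2", "rs3"),
    term = c("tA", "tA", "tB"), stringsAsFactors = FALSE),
    class = c("snp_catalog", "data.frame"))
  enr <- snp_enrichment(assoc, snps, bg, by_term = TRUE)
  expect_setequal(unique(enr$term), c("tA", "tB"))
  rowA <- enr[enr$group == "g1" & enr$term == "tA", ]
  expect_equal(rowA$score, epom_score(rowA$log10_p, 2))
})
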