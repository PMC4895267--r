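# Downstream analyses of associated regions: merging adjacent windows,
# nearest-TSS target-gene assignment, gene-set (GO/DO) enrichment, SNP
# enrichment and specificity summaries.  All enrichment p-values come
# from the same exact overlap-test engine used for EPOM scores.

#' Merge book-ended windows into maximal regions
#'
#' Adjacent windows (gap of 0 bp on the same chromosome) are merged into
#' single regions; the operation is idempotent and conserves covered bp.
#'
#' @param windows data frame with `chrom`, `start`, `end` (any order).
#' @return sorted data frame of merged regions.
#' @export
merge_adjacent <- function(windows) {
  if (!nrow(windows)) return(windows[c("chrom", "start", "end")])
  w <- sort_windows(windows)
  new_run <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                 w$start[-1] != w$end[-nrow(w)])
  run <- cumsum(new_run)
  data.frame(chrom = w$chrom[new_run],
             start = w$start[new_run],
             end = as.integer(tapply(w$end, run, max)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign potential target genes to associated regions
#'
#' Each region is related to its nearest transcription start site within
#' `max_distance` bp (default 200 kb), measuring from the region
#' midpoint.  For enhancer-class regions the nearest TSS in either
#' direction qualifies.  For promoter-class regions only genes
#' transcribed away from the region qualify (the region must lie on the
#' gene's 5' side: TSS >= midpoint for `+` genes, TSS <= midpoint for
#' `-` genes).  Equidistant ties resolve to the lexicographically
#' smallest gene id.
#'
#' @param regions data frame with `chrom`, `start`, `end` (typically
#'   from [merge_adjacent()]).
#' @param annotation a `"gene_annotation"` (see [read_tss()]).
#' @param class_label `"enhancer"` or `"promoter"`.
#' @param max_distance maximum midpoint-to-TSS distance in bp.
#' @param group optional group label copied into the result.
#' @return data frame of class `"target_assignment"` with columns
#'   `chrom`, `start`, `end`, `group`, `region_class`, `gene_id` (NA
#'   when no TSS qualifies) and `distance` (signed, `tss - midpoint`).
#' @export
assign_target_genes <- function(regions, annotation,
                                class_label = c("enhancer", "promoter"),
                                max_distance = 200000, group = NA) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!nrow(annotation)) stop("empty gene annotation")
  n <- nrow(regions)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  mid <- (regions$start + regions$end) / 2
  for (ch in unique(regions$chrom)) {
    ridx <- which(regions$chrom == ch)
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(ann)) next
    for (r in ridx) {
      m <- mid[r]
      cand <- if (class_label == "enhancer") {
        ann
      } else {
        ann[(ann$strand == "+" & ann$tss >= m) |
              (ann$strand == "-" & ann$tss <= m), , drop = FALSE]
      }
      if (!nrow(cand)) next
      d <- abs(cand$tss - m)
      ok <- d <= max_distance
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      d <- d[ok]
      best <- which(d == min(d))
      pick <- best[order(cand$gene_id[best])][1]  # deterministic tie-break
      gene[r] <- cand$gene_id[pick]
      dist[r] <- cand$tss[pick] - m
    }
  }
  structure(data.frame(chrom = regions$chrom, start = regions$start,
                       end = regions$end, group = group,
                       region_class = class_label, gene_id = gene,
                       distance = dist, stringsAsFactors = FALSE),
            class = c("target_assignment", "data.frame"))
}

#' Potential target genes for every group of a fit
#'
#' Convenience wrapper: per group, optionally merges adjacent associated
#' windows, then runs [assign_target_genes()].
#'
#' @param fit an `"epom"` fit (or an `"epom_assoc"`).
#' @param annotation a `"gene_annotation"`.
#' @param merge merge book-ended windows before assignment (default
#'   TRUE).
#' @inheritParams assign_target_genes
#' @return named list (per group) of `"target_assignment"` data frames.
#' @export
target_genes <- function(fit, annotation, merge = TRUE,
                         class_label = NULL, max_distance = 200000) {
  assoc <- if (inherits(fit, "epom")) fit$assoc else fit
  class_label <- class_label %||% assoc$region_class %||% "enhancer"
  out <- lapply(names(assoc$sets), function(g) {
    ids <- assoc$sets[[g]]
    if (!length(ids)) {
      return(assign_target_genes(
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0)),
        annotation, class_label, max_distance, group = g))
    }
    regions <- parse_window_id(ids)
    if (merge) regions <- merge_adjacent(regions)
    assign_target_genes(regions, annotation, class_label, max_distance,
                        group = g)
  })
  stats::setNames(out, names(assoc$sets))
}

#' Gene-sharing summary across groups
#'
#' For each target gene, counts the number of groups (n) in which it is
#' identified, then tabulates per group how many of its genes fall in
#' each n-bin.
#'
#' @param assignments named list of `"target_assignment"` data frames
#'   (per group), or a named list of character gene-id vectors.
#' @param breaks upper bounds of the n-bins; default `c(1, 5, Inf)`
#'   gives bins n=1, n in 2..5, n>5.
#' @return data frame with columns `group`, one count column per bin,
#'   `n_genes` and `proportion` (genes / regions, NA when region counts
#'   are unknown).
#' @export
count_gene_sharing <- function(assignments, breaks = c(1, 5, Inf)) {
  gene_sets <- lapply(assignments, function(a) {
    if (is.data.frame(a)) unique(a$gene_id[!is.na(a$gene_id)])
    else unique(a)
  })
  n_regions <- vapply(assignments, function(a) {
    if (is.data.frame(a)) nrow(a) else NA_integer_
  }, 1L)
  ## per gene: in how many groups it appears
  sharing <- table(unlist(lapply(gene_sets, unique), use.names = FALSE))
  lower <- c(1, head(breaks, -1) + 1)
  labels <- ifelse(lower == breaks, paste0("n=", breaks),
                   ifelse(is.finite(breaks),
                          paste0("n=", lower, "-", breaks),
                          paste0("n>", lower - 1)))
  counts <- t(vapply(gene_sets, function(genes) {
    s <- as.integer(sharing[genes])
    vapply(seq_along(breaks), function(b)
      sum(s >= lower[b] & s <= breaks[b]), 1L)
  }, integer(length(breaks))))
  colnames(counts) <- labels
  out <- data.frame(group = names(gene_sets), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$n_genes <- vapply(gene_sets, length, 1L)
  out$proportion <- ifelse(is.na(n_regions), NA_real_,
                           ifelse(n_regions > 0,
                                  out$n_genes / n_regions, 0))
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment of per-group target genes
#'
#' For each (group, term) pair, runs the exact overlap test with the
#' gene population as universe: A = the group's target genes restricted
#' to the population, B = the term's genes restricted to the population.
#' P-values are Bonferroni-corrected per group by the number of terms
#' tested; the enrichment score is `-log10` of the corrected p.
#'
#' @param gene_sets named list (per group) of character gene-id vectors,
#'   or the output of [target_genes()].
#' @param collection a `"gene_set_collection"` (see [read_gmt()]).
#' @param population character vector of gene ids forming the universe;
#'   default: union of all groups' gene sets.
#' @return data frame of class `"enrichment_result"` with columns
#'   `group`, `term`, `term_name`, `overlap`, `size_a`, `size_b`,
#'   `population`, `log10_p`, `score`.
#' @export
gene_set_enrichment <- function(gene_sets, collection,
                                population = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_sets <- lapply(gene_sets, function(a) {
    if (is.data.frame(a)) unique(a$gene_id[!is.na(a$gene_id)])
    else unique(a)
  })
  population <- unique(population %||%
                         unlist(gene_sets, use.names = FALSE))
  if (!length(population)) stop("empty gene population")
  n <- length(population)
  n_terms <- length(collection)
  rows <- list()
  for (g in names(gene_sets)) {
    A <- intersect(gene_sets[[g]], population)
    for (term in names(collection)) {
      B <- intersect(collection[[term]]$genes, population)
      k <- length(intersect(A, B))
      lp <- if (length(A) && length(B)) {
        overlap_log_pvalue(n, length(A), length(B), k)
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, term = term, term_name = collection[[term]]$name,
        overlap = k, size_a = length(A), size_b = length(B),
        population = n, log10_p = lp,
        score = epom_score(lp, n_terms), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("enrichment_result", "data.frame"))
}

#' Top enriched terms per group
#'
#' @param enrichment an `"enrichment_result"`.
#' @param k number of terms per group (default 10).
#' @return the enrichment rows of each group's `k` highest-scoring
#'   terms, score-descending (ties break by term id).
#' @export
top_terms <- function(enrichment, k = 10) {
  parts <- lapply(split(enrichment, enrichment$group), function(df) {
    df[order(-df$score, df$term), , drop = FALSE][seq_len(min(k, nrow(df))), ]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Proportion of group-specific enriched terms
#'
#' A term is *enriched* in a group when its raw overlap-test p-value is
#' below `p_threshold` (default 1e-3) and *specific* when it is enriched
#' in exactly one group.  Per group, reports specific / enriched (0 when
#' nothing is enriched).
#'
#' @param enrichment an `"enrichment_result"` covering >= 2 groups.
#' @param p_threshold raw p-value cutoff.
#' @return data frame with columns `group`, `n_enriched`, `n_specific`,
#'   `proportion_specific`.
#' @export
specificity_summary <- function(enrichment, p_threshold = 1e-3) {
  if (length(unique(enrichment$group)) < 2) {
    stop("specificity needs >= 2 groups")
  }
  enr <- enrichment[enrichment$log10_p < log10(p_threshold), ,
                    drop = FALSE]
  term_groups <- table(unique(enr[c("term", "group")])$term)
  rows <- lapply(unique(enrichment$group), function(g) {
    terms_g <- unique(enr$term[enr$group == g])
    n_enr <- length(terms_g)
    n_spec <- sum(term_groups[terms_g] == 1)
    data.frame(group = g, n_enriched = n_enr, n_specific = n_spec,
               proportion_specific = if (n_enr) n_spec / n_enr else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## window ids of the background windows that contain >= 1 SNP of the
## given catalog rows
snp_windows <- function(snps, background, window_size) {
  bg_ids <- window_id(background)
  snp_ids <- sprintf("%s:%d-%d", snps$chrom,
                     (snps$pos %/% window_size) * window_size,
                     (snps$pos %/% window_size) * window_size +
                       window_size)
  unique(snp_ids[snp_ids %in% bg_ids])
}

#' SNP enrichment in associated regions
#'
#' Quantifies the enrichment of trait/disease-associated SNPs in each
#' group's associated windows with the exact overlap test at window
#' level: the universe is the background (candidate) window set, A is
#' the group's associated windows, B the background windows containing
#' at least one SNP.  In global mode (`by_term = FALSE`) all SNPs count
#' and p-values are Bonferroni-corrected over groups; in per-term mode
#' each trait/disease term is tested separately, corrected over terms.
#' A SNP at position P lies in window \[start, end) iff
#' `start <= P < end`; SNPs on chromosomes absent from the background
#' are skipped with a message.
#'
#' @param assoc an `"epom_assoc"` or an `"epom"` fit.
#' @param snps a `"snp_catalog"` (see [read_snps()]).
#' @param background data frame of background (candidate) windows.
#' @param by_term per-term (DO-style) mode instead of global.
#' @param window_size unit window width (default inferred from the
#'   background windows).
#' @return an `"enrichment_result"` data frame (term = `"global"` in
#'   global mode).
#' @export
snp_enrichment <- function(assoc, snps, background, by_term = FALSE,
                           window_size = NULL) {
  if (inherits(assoc, "epom")) assoc <- assoc$assoc
  stopifnot(inherits(assoc, "epom_assoc"))
  window_size <- window_size %||%
    as.integer(stats::median(background$end - background$start))
  bg_ids <- window_id(background)
  n <- length(bg_ids)
  off <- !snps$chrom %in% background$chrom
  if (any(off)) {
    message("snp_enrichment: skipping ", sum(off),
            " SNP record(s) on chromosomes absent from the background")
    snps <- snps[!off, , drop = FALSE]
  }
  terms <- if (by_term) sort(unique(snps$term)) else "global"
  n_tests <- if (by_term) length(terms) else length(assoc$sets)
  rows <- list()
  for (term in terms) {
    sub <- if (by_term) snps[snps$term == term, , drop = FALSE] else snps
    B <- snp_windows(sub, background, window_size)
    for (g in names(assoc$sets)) {
      A <- intersect(assoc$sets[[g]], bg_ids)
      k <- length(intersect(A, B))
      lp <- if (length(A) && length(B)) {
        overlap_log_pvalue(n, length(A), length(B), k)
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, term = term, term_name = term, overlap = k,
        size_a = length(A), size_b = length(B), population = n,
        log10_p = lp, score = epom_score(lp, max(1, n_tests)),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("enrichment_result", "data.frame"))
}
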