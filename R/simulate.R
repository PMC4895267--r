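# Seeded synthetic datasets with known planted structure, used to
# validate every stage of the pipeline without external downloads.
#
# Signal is drawn at the 200 bp window level (the scale at which the
# tests operate): background values are Normal(baseline_mean, noise_sd)
# censored at 0 (signals are -log10 p-values and cannot be negative),
# and planted (group, window) pairs add effect_size to that group's
# samples.  When 25 bp tracks are emitted, each window's eight bins
# share the window value (plus optional within-window jitter), so
# averaging back to 200 bp reproduces the simulated matrix exactly.

#' Configuration for the synthetic-data generator
#'
#' @param n_groups number of biological groups (>= 2).
#' @param samples_per_group samples per group (>= 2).
#' @param n_windows number of 200 bp windows on the simulated genome.
#' @param planted_fraction_per_group fraction of windows planted with a
#'   group-specific signal increase, per group (default 0.05).
#' @param effect_size signal increase added to planted windows in the
#'   planted group's samples (default 10, in -log10 p-value units).
#' @param noise_sd standard deviation of the background noise
#'   (default 1).
#' @param baseline_mean background mean signal (default 2; comfortably
#'   above 0 so censoring at 0 is negligible).
#' @param sharing a G x G symmetric matrix (zero diagonal) of fractions:
#'   entry (i, j) is the fraction of each group's planted count that is
#'   planted jointly in groups i and j.  Default: no sharing.
#' @param marks character vector of mark names (default `"H3K4me1"`).
#' @param enhancer_fraction fraction of windows labelled with the
#'   enhancer state 13 in the segmentations; the rest get the promoter
#'   state 1 (default 1).
#' @param window_size unit window width in bp (default 200).
#' @param resolution fine track resolution in bp (default 25).
#' @param within_window_sd sd of additional 25 bp-level jitter inside a
#'   window when tracks are emitted (default 0: flat within window).
#' @param n_background_genes,n_background_terms,term_size extra
#'   unplanted annotation/gene-set material.
#' @param seed RNG seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_groups = 6, samples_per_group = 6,
                       n_windows = 10000,
                       planted_fraction_per_group = 0.05,
                       effect_size = 10, noise_sd = 1,
                       baseline_mean = 2, sharing = NULL,
                       marks = "H3K4me1", enhancer_fraction = 1,
                       window_size = 200, resolution = 25,
                       within_window_sd = 0,
                       n_background_genes = 50,
                       n_background_terms = 5, term_size = 20,
                       seed = 1) {
  stopifnot(n_groups >= 2, samples_per_group >= 2, n_windows >= 1,
            planted_fraction_per_group >= 0,
            planted_fraction_per_group < 1,
            effect_size >= 0, noise_sd > 0, baseline_mean >= 0,
            enhancer_fraction >= 0, enhancer_fraction <= 1)
  if (!is.null(sharing)) {
    sharing <- as.matrix(sharing)
    stopifnot(nrow(sharing) == n_groups, ncol(sharing) == n_groups,
              isTRUE(all.equal(sharing, t(sharing))),
              all(diag(sharing) == 0), all(sharing >= 0),
              all(sharing <= 1))
  }
  structure(as.list(environment()), class = "sim_config")
}

## Draw the planted (group -> window index) structure, honouring the
## sharing matrix: shared windows are planted in both groups of a pair.
plant_windows <- function(cfg) {
  G <- cfg$n_groups
  per_group <- round(cfg$planted_fraction_per_group * cfg$n_windows)
  planted <- rep(list(integer(0)), G)
  pool <- seq_len(cfg$n_windows)
  if (per_group == 0) return(planted)
  ## shared blocks first
  if (!is.null(cfg$sharing)) {
    for (i in seq_len(G - 1)) {
      for (j in (i + 1):G) {
        s <- round(cfg$sharing[i, j] * per_group)
        if (s == 0) next
        if (s > length(pool)) stop("infeasible sharing configuration")
        w <- sample(pool, s)
        pool <- setdiff(pool, w)
        planted[[i]] <- c(planted[[i]], w)
        planted[[j]] <- c(planted[[j]], w)
      }
    }
  }
  for (g in seq_len(G)) {
    need <- per_group - length(planted[[g]])
    if (need < 0) stop("infeasible sharing configuration")
    if (need > length(pool)) stop("planted sets exceed n_windows")
    w <- sample(pool, need)
    pool <- setdiff(pool, w)
    planted[[g]] <- sort(c(planted[[g]], w))
  }
  planted
}

#' Generate a complete synthetic dataset
#'
#' Produces, deterministically from the seed, everything the pipeline
#' consumes: a window grid with chromatin-state segmentations (state 13
#' for enhancer windows, state 1 for promoter windows, shared across
#' samples), per-mark per-sample window-level signal values, the group
#' design, a TSS annotation placing one gene near every planted window,
#' a gene-set collection with one planted term per group, a SNP catalog
#' with SNPs planted in group-specific windows, and the ground truth.
#'
#' @param cfg a `"sim_config"`.
#' @return list of class `"sim_dataset"` with elements `config`,
#'   `windows`, `segmentations`, `design`, `matrices` (one
#'   `"signal_matrix"` per mark, over all windows), `annotation`,
#'   `gene_sets`, `snps` and `truth` (list with `planted`: per-group
#'   window-id character vectors; `planted_genes`: per-group gene ids;
#'   `planted_terms`: per-group term ids; `snp_groups`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_groups
  ws <- cfg$window_size
  groups <- sprintf("group%02d", seq_len(G))
  samples <- sprintf("%s_s%02d", rep(groups, each = cfg$samples_per_group),
                     rep(seq_len(cfg$samples_per_group), G))
  design <- group_design(stats::setNames(
    rep(groups, each = cfg$samples_per_group), samples))

  windows <- data.frame(chrom = "chr1",
                        start = (seq_len(cfg$n_windows) - 1L) * ws,
                        end = seq_len(cfg$n_windows) * ws,
                        stringsAsFactors = FALSE)
  n_enh <- round(cfg$enhancer_fraction * cfg$n_windows)
  states <- c(rep(13L, n_enh), rep(1L, cfg$n_windows - n_enh))
  segmentations <- lapply(samples, function(s) {
    as_segmentation(cbind(windows, state = states), sample_id = s,
                    window_size = ws)
  })
  names(segmentations) <- samples

  planted <- plant_windows(cfg)
  planted_ids <- lapply(planted, function(i)
    window_id(windows[i, , drop = FALSE]))
  names(planted_ids) <- groups

  sample_group <- rep(seq_len(G), each = cfg$samples_per_group)
  matrices <- lapply(cfg$marks, function(mark) {
    values <- matrix(stats::rnorm(cfg$n_windows * length(samples),
                                  cfg$baseline_mean, cfg$noise_sd),
                     nrow = cfg$n_windows,
                     dimnames = list(NULL, samples))
    for (g in seq_len(G)) {
      cols <- which(sample_group == g)
      values[planted[[g]], cols] <- values[planted[[g]], cols] +
        cfg$effect_size
    }
    values <- pmax(values, 0)  # censor at 0: -log10 p-values
    signal_matrix(values, windows, design, mark = mark,
                  class_label = if (cfg$enhancer_fraction >= 0.5)
                    "enhancer" else "promoter")
  })
  names(matrices) <- cfg$marks

  ## one gene near each planted window (within 200 kb), plus background
  planted_all <- sort(unique(unlist(planted)))
  gene_rows <- list()
  planted_genes <- stats::setNames(rep(list(character(0)), G), groups)
  if (length(planted_all)) {
    mid <- (windows$start[planted_all] + windows$end[planted_all]) / 2
    ## TSS close to its window (well within 200 kb) so nearest-TSS
    ## assignment can recover the planted gene on a dense toy genome
    offset <- sample(c(-1, 1), length(planted_all), TRUE) *
      sample(200:2000, length(planted_all), TRUE)
    gid <- sprintf("PG%05d", seq_along(planted_all))
    gene_rows[[1]] <- data.frame(
      gene_id = gid, chrom = "chr1",
      tss = pmax(0L, as.integer(round(mid + offset))),
      strand = sample(c("+", "-"), length(planted_all), TRUE),
      stringsAsFactors = FALSE)
    for (g in seq_len(G)) {
      planted_genes[[g]] <- gid[match(planted[[g]], planted_all)]
    }
  }
  if (cfg$n_background_genes > 0) {
    span <- cfg$n_windows * ws
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = sprintf("BG%05d", seq_len(cfg$n_background_genes)),
      chrom = "chr1",
      tss = sample(0:max(span - 1, 1), cfg$n_background_genes, TRUE),
      strand = sample(c("+", "-"), cfg$n_background_genes, TRUE),
      stringsAsFactors = FALSE)
  }
  annotation <- gene_annotation(do.call(rbind, gene_rows))

  ## gene sets: one planted term per group (that group's planted genes)
  ## plus random background terms
  sets <- list()
  planted_terms <- stats::setNames(rep(list(character(0)), G), groups)
  for (g in seq_len(G)) {
    if (!length(planted_genes[[g]])) next
    id <- sprintf("TERM_%s", groups[g])
    sets[[id]] <- list(name = paste("planted term for", groups[g]),
                       genes = planted_genes[[g]])
    planted_terms[[g]] <- id
  }
  for (b in seq_len(cfg$n_background_terms)) {
    sets[[sprintf("TERM_BG%03d", b)]] <- list(
      name = sprintf("background term %d", b),
      genes = sample(annotation$gene_id,
                     min(cfg$term_size, nrow(annotation))))
  }
  gene_sets <- structure(sets, class = "gene_set_collection")

  ## SNPs planted inside group 1's planted windows
  snp_groups <- 1L
  snp_rows <- list()
  for (g in snp_groups) {
    if (!length(planted[[g]])) next
    w <- planted[[g]]
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      chrom = "chr1",
      pos = windows$start[w] + sample(0:(ws - 1), length(w), TRUE),
      snp_id = sprintf("rs%s_%05d", groups[g], seq_along(w)),
      term = paste0("trait_", groups[g]),
      stringsAsFactors = FALSE)
  }
  snps <- structure(
    if (length(snp_rows)) do.call(rbind, snp_rows) else
      data.frame(chrom = character(0), pos = integer(0),
                 snp_id = character(0), term = character(0)),
    class = c("snp_catalog", "data.frame"))

  structure(list(config = cfg, windows = windows,
                 segmentations = segmentations, design = design,
                 matrices = matrices, annotation = annotation,
                 gene_sets = gene_sets, snps = snps,
                 truth = list(planted = planted_ids,
                              planted_genes = planted_genes,
                              planted_terms = planted_terms,
                              snp_groups = groups[snp_groups])),
            class = "sim_dataset")
}

#' Generate a null dataset (no planted effects)
#'
#' @param cfg a `"sim_config"`; its `planted_fraction_per_group` is
#'   forced to 0.
#' @return a `"sim_dataset"` (see [simulate_dataset()]).
#' @export
simulate_null <- function(cfg) {
  cfg$planted_fraction_per_group <- 0
  cfg$sharing <- NULL
  simulate_dataset(cfg)
}

#' Expand a simulated signal matrix into fine-resolution tracks
#'
#' Emits one `"signal_track"` per sample at `resolution` bp, where the
#' bins inside each window share the window's value plus optional
#' jitter (`within_window_sd`), exercising the same compression path
#' real tracks go through.
#'
#' @param sim a `"sim_dataset"`.
#' @param mark which mark's matrix to expand (default the first).
#' @return named list of `"signal_track"` objects.
#' @export
sim_tracks <- function(sim, mark = names(sim$matrices)[1]) {
  cfg <- sim$config
  sm <- sim$matrices[[mark]]
  factor <- cfg$window_size %/% cfg$resolution
  lapply(stats::setNames(sm$samples, sm$samples), function(s) {
    v <- rep(sm$values[, s], each = factor)
    if (cfg$within_window_sd > 0) {
      ## zero-mean jitter within each window so the window mean is kept
      j <- matrix(stats::rnorm(length(v), 0, cfg$within_window_sd),
                  nrow = factor)
      j <- sweep(j, 2, colMeans(j))
      v <- pmax(v + as.vector(j), 0)
    }
    structure(list(sample_id = s, mark = mark,
                   resolution = cfg$resolution,
                   values = list(chr1 = v)),
              class = "signal_track")
  })
}

#' Write a simulated dataset to disk in the package's input formats
#'
#' Emits exactly the formats the readers consume: BED4 segmentations,
#' bedGraph tracks (at fine resolution), the design TSV, the TSS table,
#' the GMT collection, the SNP TSV and a manifest recording the
#' configuration, so tests can exercise the real I/O path.
#'
#' @param sim a `"sim_dataset"`.
#' @param dir output directory (created if needed).
#' @param tracks emit per-sample bedGraph tracks (default TRUE; these
#'   dominate the output size).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(sim, dir, tracks = TRUE) {
  cfg <- sim$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$segmentations)) {
    seg <- sim$segmentations[[s]]$windows
    utils::write.table(seg, file.path(dir, paste0(s, ".segmentation.bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(sim$design,
                     file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sim$annotation$gene_id, sim$annotation$chrom,
               sim$annotation$tss, sim$annotation$strand),
    file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(sim$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (tracks) {
    for (mark in names(sim$matrices)) {
      trs <- sim_tracks(sim, mark)
      for (s in names(trs)) {
        v <- trs[[s]]$values$chr1
        bg <- data.frame(chrom = "chr1",
                         start = (seq_along(v) - 1L) * cfg$resolution,
                         end = seq_along(v) * cfg$resolution,
                         value = v)
        utils::write.table(bg,
                           file.path(dir, paste0(s, ".", mark, ".bedgraph")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    }
  }
  manifest <- c(
    sprintf("seed\t%d", cfg$seed),
    sprintf("n_groups\t%d", cfg$n_groups),
    sprintf("samples_per_group\t%d", cfg$samples_per_group),
    sprintf("n_windows\t%d", cfg$n_windows),
    sprintf("planted_fraction_per_group\t%g",
            cfg$planted_fraction_per_group),
    sprintf("effect_size\t%g", cfg$effect_size),
    sprintf("noise_sd\t%g", cfg$noise_sd),
    sprintf("baseline_mean\t%g", cfg$baseline_mean),
    sprintf("marks\t%s", paste(cfg$marks, collapse = ",")))
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  for (g in names(sim$truth$planted)) {
    ids <- sim$truth$planted[[g]]
    w <- if (length(ids)) parse_window_id(ids) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0))
    write_regions(w, file.path(dir, paste0("truth_", g, ".bed")))
  }
  invisible(dir)
}

#' Sensitivity and precision of planted-window recovery
#'
#' Compares the per-group associated window sets of a fit against the
#' planted truth over (group, window) pairs: sensitivity is the
#' fraction of planted pairs recovered, precision the fraction of
#' reported pairs that were planted.
#'
#' @param fit an `"epom"` fit or an `"epom_assoc"`.
#' @param truth named list (per group) of planted window-id vectors,
#'   e.g. `sim$truth$planted`.
#' @return list with `sensitivity`, `precision`, `tp`, `fp`, `fn`.
#' @export
recovery_stats <- function(fit, truth) {
  sets <- if (inherits(fit, "epom")) fit$assoc$sets else fit$sets
  groups <- intersect(names(truth), names(sets))
  tp <- fp <- fn <- 0L
  for (g in groups) {
    found <- sets[[g]]
    planted <- truth[[g]]
    tp <- tp + length(intersect(found, planted))
    fp <- fp + length(setdiff(found, planted))
    fn <- fn + length(setdiff(planted, found))
  }
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
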