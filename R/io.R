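# Readers and writers for the plain-text genomic formats the pipeline
# touches.  All coordinates are 0-based half-open (BED convention)
# throughout the package; any 1-based dialect must be converted at this
# boundary.

read_table_nocomment <- function(path, ...) {
  utils::read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

#' Read a chromatin-state segmentation (BED4)
#'
#' Parses a BED4-style file of `chrom start end state` records into unit
#' windows on a fixed grid.  The state column may be a bare number
#' (`"13"`) or a mnemonic with a leading integer (`"E13"`, `"13_EnhA1"`);
#' the leading integer is extracted and must lie in `1..n_states`.
#' Records spanning several grid windows (width a multiple of
#' `window_size`) are split into unit windows sharing the record's state.
#'
#' @param path path to a whitespace/tab separated BED4 file; lines
#'   starting with `#` are ignored.
#' @param sample_id sample identifier attached to the segmentation;
#'   defaults to the file name without extension.
#' @param window_size unit window width in bp (default 200).
#' @param n_states number of states in the chromatin-state model
#'   (default 25).
#' @return an object of class `"chrom_segmentation"`: a list with
#'   `sample_id`, `window_size` and `windows`, a data frame with columns
#'   `chrom`, `start`, `end`, `state`, sorted and non-overlapping within
#'   each chromosome.
#' @export
read_segmentation <- function(path, sample_id = NULL, window_size = 200,
                              n_states = 25) {
  tab <- read_table_nocomment(path)
  if (ncol(tab) < 4) stop("segmentation file needs 4 columns: ", path)
  seg <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    state_token = as.character(tab[[4]]),
                    stringsAsFactors = FALSE)
  as_segmentation(seg, sample_id = sample_id %||%
                    sub("\\.[^.]*$", "", basename(path)),
                  window_size = window_size, n_states = n_states)
}

## Build/validate a chrom_segmentation from a chrom/start/end/state(_token)
## data frame; splits multi-window records into unit windows.
as_segmentation <- function(seg, sample_id, window_size = 200,
                            n_states = 25) {
  if (is.null(seg[["state"]])) {
    m <- regmatches(seg$state_token,
                    regexpr("[0-9]+", seg$state_token))
    if (length(m) != nrow(seg)) {
      stop("state token without a leading integer in segmentation")
    }
    seg$state <- as.integer(m)
  }
  if (any(seg$state < 1 | seg$state > n_states)) {
    stop("chromatin state outside 1..", n_states)
  }
  if (any(seg$start < 0) || any(seg$end <= seg$start)) {
    stop("invalid interval coordinates in segmentation")
  }
  widths <- seg$end - seg$start
  if (any(widths %% window_size != 0) ||
      any(seg$start %% window_size != 0)) {
    stop("segmentation records must align to the ", window_size,
         " bp grid")
  }
  ## split multi-window records into unit windows
  nrep <- widths %/% window_size
  idx <- rep.int(seq_len(nrow(seg)), nrep)
  off <- (sequence(nrep) - 1L) * window_size
  windows <- data.frame(
    chrom = seg$chrom[idx],
    start = seg$start[idx] + off,
    end = seg$start[idx] + off + window_size,
    state = seg$state[idx],
    stringsAsFactors = FALSE
  )
  windows <- sort_windows(windows)
  dup <- duplicated(windows[c("chrom", "start")])
  if (any(dup)) stop("overlapping segmentation records")
  structure(list(sample_id = sample_id, window_size = window_size,
                 windows = windows),
            class = "chrom_segmentation")
}

#' Read a binned signal track (bedGraph or fixedStep wiggle)
#'
#' Signal values are -log10 enrichment p-values and must be finite and
#' non-negative.  The result is a dense per-chromosome vector at the
#' stated resolution; gaps between intervals are filled with 0 (a message
#' reports how many bins were filled).
#'
#' @param path bedGraph (`chrom start end value`) or fixedStep wiggle
#'   file.  bedGraph intervals must have widths that are multiples of
#'   `resolution`; fixedStep headers must use `step` equal to
#'   `resolution`.
#' @param resolution bin width in bp (default 25).
#' @param sample_id,mark identifiers attached to the track.
#' @return an object of class `"signal_track"`: list with `sample_id`,
#'   `mark`, `resolution` and `values`, a named list of numeric vectors
#'   (one per chromosome; element `i` covers
#'   `[(i-1)*resolution, i*resolution)`).
#' @export
read_signal <- function(path, resolution = 25, sample_id = NULL,
                        mark = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("empty signal file: ", path)
  if (any(startsWith(lines, "fixedStep"))) {
    values <- parse_fixedstep(lines, resolution)
  } else {
    values <- parse_bedgraph(lines, resolution)
  }
  for (v in values) {
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("signal values must be finite and >= 0 (-log10 p-values)")
    }
  }
  structure(list(sample_id = sample_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 mark = mark, resolution = resolution, values = values),
            class = "signal_track")
}

parse_bedgraph <- function(lines, resolution) {
  tab <- utils::read.table(text = lines, header = FALSE,
                           stringsAsFactors = FALSE)
  chrom <- as.character(tab[[1]])
  start <- as.integer(tab[[2]])
  end <- as.integer(tab[[3]])
  val <- as.numeric(tab[[4]])
  if (any((end - start) %% resolution != 0) ||
      any(start %% resolution != 0)) {
    stop("bedGraph intervals must align to the ", resolution, " bp grid")
  }
  out <- list()
  filled <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    i <- i[order(start[i])]
    len <- max(end[i]) %/% resolution
    v <- numeric(len)  # gaps default to 0
    covered <- logical(len)
    for (j in i) {
      bins <- (start[j] %/% resolution + 1L):(end[j] %/% resolution)
      if (any(covered[bins])) stop("overlapping bedGraph intervals on ", ch)
      v[bins] <- val[j]
      covered[bins] <- TRUE
    }
    filled <- filled + sum(!covered)
    out[[ch]] <- v
  }
  if (filled > 0) {
    message("read_signal: filled ", filled, " uncovered bin(s) with 0")
  }
  out
}

parse_fixedstep <- function(lines, resolution) {
  hdr <- grep("^fixedStep", lines)
  if (!length(hdr)) stop("no fixedStep header")
  bounds <- c(hdr, length(lines) + 1L)
  out <- list()
  for (b in seq_along(hdr)) {
    h <- lines[hdr[b]]
    fields <- strsplit(h, "[ \t]+")[[1]][-1]
    kv <- strsplit(fields, "=")
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    ch <- vals[keys == "chrom"]
    step <- as.integer(vals[keys == "step"])
    span <- if ("span" %in% keys) as.integer(vals[keys == "span"]) else step
    start1 <- as.integer(vals[keys == "start"])  # wiggle is 1-based
    if (step != resolution || span != resolution) {
      stop("fixedStep step/span must equal the stated resolution")
    }
    body <- lines[(hdr[b] + 1L):(bounds[b + 1L] - 1L)]
    v <- as.numeric(body)
    start0 <- start1 - 1L
    if (start0 %% resolution != 0) {
      stop("fixedStep start must align to the ", resolution, " bp grid")
    }
    prev <- out[[ch]] %||% numeric(0)
    need <- start0 %/% resolution
    if (length(prev) < need) prev <- c(prev, numeric(need - length(prev)))
    out[[ch]] <- c(prev[seq_len(need)], v)
  }
  out
}

#' Read a sample-to-group design table
#'
#' Two-column TSV (`sample_id<TAB>group`, optional header).  Groups with
#' fewer than `min_group_size` samples are dropped with a warning, since
#' group-wise variances are undefined for singleton groups.
#'
#' @param path TSV path.
#' @param min_group_size smallest retained group (default 2).
#' @return object of class `"group_design"`: data frame with columns
#'   `sample_id`, `group` (character), attribute `dropped` listing the
#'   removed samples.
#' @export
read_design <- function(path, min_group_size = 2) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (tolower(tab[1, 1]) %in% c("sample", "sample_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  group_design(stats::setNames(as.character(tab[[2]]),
                               as.character(tab[[1]])),
               min_group_size = min_group_size)
}

#' Construct a group design from a named vector
#'
#' @param groups named character vector: `names` are sample ids, values
#'   are group labels.
#' @param min_group_size smallest retained group (default 2); smaller
#'   groups are dropped with a warning.
#' @return object of class `"group_design"` (see [read_design()]).
#' @export
group_design <- function(groups, min_group_size = 2) {
  if (anyDuplicated(names(groups))) stop("duplicate sample ids in design")
  df <- data.frame(sample_id = names(groups),
                   group = unname(as.character(groups)),
                   stringsAsFactors = FALSE)
  sizes <- table(df$group)
  small <- names(sizes)[sizes < min_group_size]
  dropped <- df$sample_id[df$group %in% small]
  if (length(dropped)) {
    warning("dropping ", length(small), " group(s) with < ",
            min_group_size, " samples: ", paste(small, collapse = ", "))
    df <- df[!df$group %in% small, , drop = FALSE]
  }
  if (!nrow(df)) stop("no groups left after dropping small groups")
  rownames(df) <- NULL
  structure(df, class = c("group_design", "data.frame"),
            dropped = dropped)
}

#' Read a TSS-level gene annotation
#'
#' Accepts a 4-column TSV (`gene_id chrom tss strand`) or BED6
#' (`chrom start end name score strand`; the TSS is `start` for `+`
#' genes and `end - 1` for `-` genes).
#'
#' @param path annotation path.
#' @param format `"tsv"` or `"bed6"`.
#' @return data frame of class `"gene_annotation"` with columns
#'   `gene_id`, `chrom`, `tss` (0-based bp), `strand`.
#' @export
read_tss <- function(path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  tab <- read_table_nocomment(path)
  if (format == "bed6") {
    if (ncol(tab) < 6) stop("BED6 needs 6 columns")
    strand <- as.character(tab[[6]])
    ann <- data.frame(gene_id = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      tss = ifelse(strand == "+", as.integer(tab[[2]]),
                                   as.integer(tab[[3]]) - 1L),
                      strand = strand, stringsAsFactors = FALSE)
  } else {
    if (ncol(tab) < 4) stop("TSS table needs 4 columns")
    ann <- data.frame(gene_id = as.character(tab[[1]]),
                      chrom = as.character(tab[[2]]),
                      tss = as.integer(tab[[3]]),
                      strand = as.character(tab[[4]]),
                      stringsAsFactors = FALSE)
  }
  gene_annotation(ann)
}

#' @rdname read_tss
#' @param ann data frame with columns `gene_id`, `chrom`, `tss`,
#'   `strand` to validate and classify.
#' @export
gene_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotation")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(ann$tss < 0)) stop("TSS positions must be non-negative")
  rownames(ann) <- NULL
  structure(ann, class = c("gene_annotation", "data.frame"))
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of class `"gene_set_collection"`; each element is
#'   `list(name = description, genes = character vector)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with empty gene set: ", f[1])
    list(name = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate term ids in GMT")
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param sets a `"gene_set_collection"` (see [read_gmt()]).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP catalog
#'
#' TSV with columns `chrom position snp_id term`; positions are 0-based.
#' A SNP carrying several trait/disease terms appears once per term.
#'
#' @param path TSV path.
#' @return data frame of class `"snp_catalog"` with columns `chrom`,
#'   `pos`, `snp_id`, `term`.
#' @export
read_snps <- function(path) {
  tab <- read_table_nocomment(path, sep = "\t")
  if (ncol(tab) < 4) stop("SNP catalog needs 4 columns")
  snps <- data.frame(chrom = as.character(tab[[1]]),
                     pos = as.integer(tab[[2]]),
                     snp_id = as.character(tab[[3]]),
                     term = as.character(tab[[4]]),
                     stringsAsFactors = FALSE)
  if (any(snps$pos < 0)) stop("SNP positions must be non-negative")
  structure(snps, class = c("snp_catalog", "data.frame"))
}

#' Write/read window lists as BED3 (+ optional group column)
#'
#' `write_regions()` writes `chrom start end [group]`;
#' `read_regions()` reads it back.  The pair round-trips exactly.
#'
#' @param windows data frame with columns `chrom`, `start`, `end` and
#'   optionally `group`.
#' @param path BED path.
#' @param header optional character vector of comment lines (each will
#'   be prefixed with `#`) written before the records.
#' @return `read_regions()` returns the window data frame (with `group`
#'   when present in the file).
#' @export
write_regions <- function(windows, path, header = NULL) {
  cols <- intersect(c("chrom", "start", "end", "group"), names(windows))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(windows[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  tab <- read_table_nocomment(path)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$group <- as.character(tab[[4]])
  out
}
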