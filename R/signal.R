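# Candidate-window selection from chromatin states and assembly of
# per-mark region x sample signal matrices.

#' Chromatin-state sets defining candidate enhancers and promoters
#'
#' Default state numbers for the 25-state chromatin model: enhancer
#' states 10-18 (transcription 5'/3'/weak enhancers, active enhancers
#' 1-2, enhancer flank, weak enhancers 1-2, enhancer acetylation only)
#' and promoter states 1-4, 22, 23 (active TSS, promoter up/downstream
#' TSS, poised and bivalent promoters).
#'
#' @param label `"enhancer"` or `"promoter"`.
#' @param states optional integer vector overriding the default state
#'   set.
#' @return list of class `"region_class"` with `label` and `states`.
#' @export
region_class <- function(label = c("enhancer", "promoter"),
                         states = NULL) {
  label <- match.arg(label)
  default <- switch(label,
                    enhancer = 10:18,
                    promoter = c(1:4, 22L, 23L))
  structure(list(label = label, states = as.integer(states %||% default)),
            class = "region_class")
}

#' Average a fine-resolution signal track into coarser bins
#'
#' Compresses a binned track by averaging every `factor` consecutive
#' values, e.g. eight 25 bp bins into one 200 bp bin.  The mean (and the
#' total mass, up to the factor) is conserved exactly.
#'
#' @param track a `"signal_track"` (see [read_signal()]).
#' @param factor number of consecutive input bins per output bin
#'   (default 8).
#' @param truncate_tail drop a trailing partial block instead of
#'   erroring when a chromosome length is not a multiple of `factor`.
#' @return a `"signal_track"` at `resolution * factor`.
#' @export
compress_to_windows <- function(track, factor = 8, truncate_tail = FALSE) {
  stopifnot(inherits(track, "signal_track"), factor >= 1)
  factor <- as.integer(factor)
  values <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    r <- length(v) %% factor
    if (r != 0) {
      if (!truncate_tail) {
        stop("length of ", ch, " (", length(v),
             ") is not a multiple of ", factor,
             "; set truncate_tail = TRUE to drop the partial block")
      }
      message("compress_to_windows: dropping ", r, " trailing bin(s) on ",
              ch)
      v <- v[seq_len(length(v) - r)]
    }
    if (!length(v)) return(numeric(0))
    colMeans(matrix(v, nrow = factor))
  })
  names(values) <- names(track$values)
  structure(list(sample_id = track$sample_id, mark = track$mark,
                 resolution = track$resolution * factor, values = values),
            class = "signal_track")
}

#' Select candidate enhancer or promoter windows from segmentations
#'
#' A window is a candidate for a region class when it carries one of the
#' class's chromatin states in at least `min_samples` of the given
#' per-sample segmentations (default 1, i.e. the union over samples).
#'
#' @param segmentations list of `"chrom_segmentation"` objects sharing
#'   the same window grid.
#' @param class a `"region_class"` (see [region_class()]).
#' @param min_samples minimum number of samples in which a window must
#'   carry a class state (default 1).
#' @return sorted data frame with columns `chrom`, `start`, `end`.
#' @export
select_candidate_windows <- function(segmentations, class,
                                     min_samples = 1) {
  if (!length(segmentations)) stop("no segmentations given")
  stopifnot(inherits(class, "region_class"))
  per_sample <- lapply(segmentations, function(seg) {
    w <- seg$windows
    unique(window_id(w[w$state %in% class$states, , drop = FALSE]))
  })
  counts <- table(unlist(per_sample, use.names = FALSE))
  ids <- names(counts)[counts >= min_samples]
  if (!length(ids)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  sort_windows(parse_window_id(ids))
}

#' Assemble a region x sample signal matrix for one mark
#'
#' Looks up each candidate window's value in each sample's track.  The
#' tracks must already be at window resolution (compress first with
#' [compress_to_windows()]).  Windows falling beyond a track's recorded
#' length take value 0, mirroring the gap rule of [read_signal()].
#'
#' @param tracks list of `"signal_track"` objects, one per sample in the
#'   design, all for the same mark; names or `sample_id` fields identify
#'   the samples.
#' @param windows candidate window data frame (`chrom`, `start`, `end`).
#' @param design a `"group_design"`.
#' @param mark mark label stored in the result (defaults to the tracks'
#'   common mark).
#' @param class_label region-class label stored in the result.
#' @return object of class `"signal_matrix"`: list with `mark`,
#'   `region_class`, `windows`, `samples`, `values` (windows x samples
#'   numeric matrix) and `design`.
#' @export
build_signal_matrix <- function(tracks, windows, design, mark = NULL,
                                class_label = NULL) {
  stopifnot(inherits(design, "group_design"))
  ids <- vapply(tracks, function(t) t$sample_id, "")
  names(tracks) <- ids
  missing <- setdiff(design$sample_id, ids)
  if (length(missing)) {
    stop("no signal track for sample(s): ", paste(missing, collapse = ", "))
  }
  samples <- sort(design$sample_id)  # canonical order
  check_window_grid(windows, tracks[[1]]$resolution)
  values <- matrix(0, nrow = nrow(windows), ncol = length(samples),
                   dimnames = list(window_id(windows), samples))
  n_off <- 0L
  for (s in samples) {
    tr <- tracks[[s]]
    bin <- windows$start %/% tr$resolution + 1L
    for (ch in unique(windows$chrom)) {
      i <- windows$chrom == ch
      v <- tr$values[[ch]] %||% numeric(0)
      inside <- bin[i] <= length(v)
      vals <- numeric(sum(i))
      vals[inside] <- v[bin[i][inside]]
      n_off <- n_off + sum(!inside)
      values[i, s] <- vals
    }
  }
  if (n_off > 0) {
    message("build_signal_matrix: ", n_off,
            " window/sample value(s) beyond track end set to 0")
  }
  signal_matrix(values, windows, design, mark = mark %||% tracks[[1]]$mark,
                class_label = class_label)
}

#' @rdname build_signal_matrix
#' @param values windows x samples numeric matrix (column names are
#'   sample ids) for direct construction.
#' @export
signal_matrix <- function(values, windows, design, mark = NULL,
                          class_label = NULL) {
  stopifnot(inherits(design, "group_design"),
            is.matrix(values), nrow(values) == nrow(windows))
  if (is.null(colnames(values))) {
    stop("signal matrix needs sample ids as column names")
  }
  if (!setequal(colnames(values), design$sample_id)) {
    stop("matrix columns do not match design samples")
  }
  values <- values[, sort(design$sample_id), drop = FALSE]
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("signal values must be finite and >= 0")
  }
  rownames(values) <- window_id(windows)
  structure(list(mark = mark, region_class = class_label,
                 windows = windows, samples = colnames(values),
                 values = values, design = design),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$values), "windows x", ncol(x$values),
      "samples", if (!is.null(x$mark)) paste0("(", x$mark, ")"), "\n")
  grp <- x$design$group[match(x$samples, x$design$sample_id)]
  cat("  groups:", paste(names(table(grp)), table(grp), sep = ":",
                         collapse = " "), "\n")
  invisible(x)
}

## group factor aligned with the matrix columns
matrix_groups <- function(sm) {
  factor(sm$design$group[match(sm$samples, sm$design$sample_id)])
}
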