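# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

## log(sum(exp(x))) without overflow; x in natural log space
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Canonical string id for a genomic window, used wherever windows are
## treated as set elements.
window_id <- function(windows) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  sprintf("%s:%d-%d", windows$chrom, as.integer(windows$start),
          as.integer(windows$end))
}

## Inverse of window_id()
parse_window_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed window id(s): ", paste(head(ids[bad]), collapse = ", "))
  }
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end   = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

## Sort a window data frame by (chrom, start); chromosome order is
## lexicographic with numeric-aware suffixes (chr2 before chr10).
sort_windows <- function(windows) {
  key <- chrom_sort_key(windows$chrom)
  windows[order(key, windows$start), , drop = FALSE]
}

chrom_sort_key <- function(chrom) {
  suffix <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(suffix))
  ## numeric chromosomes first in numeric order, then others alphabetically
  alpha <- match(suffix, sort(unique(suffix[is.na(num)])))
  ifelse(is.na(num), 1e6 + alpha, num)
}

check_window_grid <- function(windows, window_size) {
  widths <- windows$end - windows$start
  if (any(widths != window_size)) {
    stop("window width != ", window_size, " bp for ",
         sum(widths != window_size), " window(s)")
  }
  if (any(windows$start %% window_size != 0)) {
    stop("window start not a multiple of ", window_size, " bp for ",
         sum(windows$start %% window_size != 0), " window(s)")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
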