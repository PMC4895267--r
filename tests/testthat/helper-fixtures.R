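# Shared fixtures and independent oracles, all built in code.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## toy group design: G groups x n samples, labels g1..gG
toy_design <- function(G = 3, n = 3) {
  samples <- sprintf("g%d_s%d", rep(seq_len(G), each = n),
                     rep(seq_len(n), G))
  group_design(stats::setNames(rep(sprintf("g%d", seq_len(G)), each = n),
                               samples))
}

## windows on the 200 bp grid of chr1
toy_windows <- function(W, window_size = 200) {
  data.frame(chrom = "chr1",
             start = as.integer((seq_len(W) - 1L) * window_size),
             end = as.integer(seq_len(W) * window_size),
             stringsAsFactors = FALSE)
}

## sample one element from a vector (sample() misreads length-1 vectors)
sample1 <- function(x) x[sample.int(length(x), 1L)]

## hand-built fine-resolution track on chr1
make_track <- function(values, resolution = 25, sample_id = "s1") {
  structure(list(sample_id = sample_id, mark = "H3K4me1",
                 resolution = resolution,
                 values = list(chr1 = values)),
            class = "signal_track")
}

toy_matrix <- function(values, design, window_size = 200, mark = "H3K4me1",
                       class_label = "enhancer") {
  colnames(values) <- design$sample_id
  signal_matrix(values, toy_windows(nrow(values), window_size), design,
                mark = mark, class_label = class_label)
}

## Independent oracle for the overlap test: exact integer enumeration of
## the trinomial/binomial tail.  For n <= 15 every binomial product is an
## exact integer below 2^53, so the sum is computed in exact arithmetic
## with a single final division.
oracle_overlap_log10p <- function(n, a, b, k) {
  i <- k:min(a, b)
  num <- sum(choose(n, i) * choose(n - i, a - i) * choose(n - a, b - i))
  den <- choose(n, a) * choose(n, b)
  log10(num) - log10(den)
}

## hypergeometric point mass, independent route via dhyper
hyper_point_mass <- function(n, a, b, k) {
  stats::dhyper(k, a, n - a, b)
}
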