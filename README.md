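# epom

Epigenome Overlap Measure (EPOM): compare tissue and cell types by the
overlap of their associated enhancer and promoter regions, derived from
histone-modification signal over chromatin-state-defined candidate
windows.

## What it does

Chromatin-state segmentations (25-state model, 200 bp windows) define
candidate enhancers (states 10–18) and candidate promoters (states 1–4,
22, 23). Per-sample histone-mark signal tracks (−log10 enrichment
p-values at 25 bp) are compressed to the same 200 bp grid by averaging.
Groups of samples (tissues or cell types) are then compared in three
steps:

1. **ANOVA filter** — for every candidate window, a one-way
   fixed-effects ANOVA across groups; windows pass if the
   Bonferroni-corrected p-value is below `alpha1` (default 1e-10, the
   correction factor being the number of windows tested).
2. **Pairwise association** — for each surviving window and each
   ordered group pair (i, j), a one-sided Welch t-test of H0: μi ≤ μj
   at raw level `alpha2` (default 0.01). A window is *associated* with
   group i when its rejection count over the other groups exceeds `m`
   (default 14, matching 16-group analyses; an `m_rule = "geq"` variant
   accepts exactly `m` rejections, which lets a window shared by two
   groups be associated with both).
3. **Overlap test** — for every group pair, the exact probability that
   two associated-region sets of the observed sizes share at least the
   observed number of windows, drawn from the population of all
   associated windows. The EPOM score is
   `max(0, −log10 p − log10 #tests)` with a Bonferroni factor of
   G(G−1)/2 over the off-diagonal pairs; diagonals carry the
   uncorrected self-overlap. Scores are conventionally saturated at 20
   for display.

The overlap p-value is computed by hand in log space (`lgamma` plus
log-sum-exp), so it is exact down to scores of many hundreds without
underflow. Downstream helpers assign associated regions to target genes
by nearest TSS within 200 kb (promoters restricted to the downstream
gene), score gene-set and SNP enrichment with the same overlap engine,
and summarise mark choice by differential-region counts.

## Quick start

Everything is testable offline through the seeded generator, which
plants group-specific high-signal windows (and, optionally, windows
shared between chosen pairs) into otherwise-null data:

```r
library(epom)

sharing <- matrix(0, 4, 4)
sharing[1, 2] <- sharing[2, 1] <- 0.5  # groups 1 and 2 share 50%

sim <- simulate_dataset(sim_config(n_groups = 4, samples_per_group = 5,
                                   n_windows = 2000, sharing = sharing,
                                   seed = 3))
fit <- epom(sim$matrices, alpha1 = 1e-4, m = 2, m_rule = "geq")
fit
#> EPOM fit (1 mark(s), combine = union)
#>   thresholds: alpha1 = 0.0001, alpha2 = 0.01, m = 2 (geq)
#>   candidates: 2000  population: 349
#> EPOM score matrix: 4 groups, population of 349 regions (Bonferroni factor 6 )
#>         group01 group02 group03 group04
#> group01   89.86    6.94    0.00    0.00
#> group02    6.94   89.47    0.00    0.00
#> group03    0.00    0.00   89.86    0.00
#> group04    0.00    0.00    0.00   89.07
```

The planted 50% sharing between groups 1 and 2 surfaces as the only
non-zero off-diagonal score. `summary(fit)` reports per-group
associated counts and top pairs, `coef(fit)` / `as.matrix(fit)` return
the score matrix, `plot(fit)` draws the saturated heatmap, and
`export_associated_regions(fit, dir)` writes the per-group BED files.

On real data, start from files instead:

```r
segs  <- lapply(seg_paths, read_segmentation)
design <- read_design("design.tsv")
cand  <- select_candidate_windows(segs, region_class("enhancer"))
tracks <- lapply(track_paths, read_signal)           # 25 bp bedGraph/wig
tracks <- lapply(tracks, compress_to_windows)        # -> 200 bp
mat   <- build_signal_matrix(tracks, cand, design, mark = "H3K4me1",
                             class_label = "enhancer")
fit   <- epom(list(H3K4me1 = mat))
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "epom.R", package = "epom")` with subcommands
`simulate`, `candidates`, `associate`, `epom`, `targets`, and `enrich`.

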