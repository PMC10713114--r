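# cytopipe

cytopipe is an R package for processing and analysing flow and mass
cytometry data end to end, without interactive tooling: reading FCS
3.0/3.1 files, channel subsetting and renaming, display transformations
(logicle / biexponential / arcsinh), spillover compensation, landmark
peak normalization across samples, declarative gating trees, balanced
non-destructive downsampling, percentile rescaling, cell-wise dataset
splitting, UMAP embedding, a guided semi-supervised clustering method,
and statistical reporting (phenotype and abundance tables, sample-level
embeddings with outlier flagging, nonparametric group comparisons, ROC
analyses). It is aimed at analysts who want a scriptable, reproducible
pipeline for multi-sample, multi-group cytometry cohorts — every step is
driven by code or config files, seeded, and logged in per-sample
provenance.

## The clustering method

The core method labels every cell in four stages:

1. **Hierarchical training** — a seeded subset (default 10%) of the
   downsampled cells is clustered agglomeratively (Ward linkage,
   Euclidean distance on rescaled channels) and cut into `K_init`
   (default 100) fine clusters.
2. **kNN propagation** — each remaining cell takes the majority label of
   its `k` (default 11) nearest training cells; ties fall back to the
   nearest neighbour, so assignment is deterministic.
3. **Binarization** — each fine cluster becomes a bit vector of marker
   positivity: bit *c* is 1 iff more than half its cells exceed the
   channel-*c* threshold (estimated from the pooled density's bimodal
   valley, or user-supplied).
4. **Binary-proximity collapsing** — clusters with identical bit vectors
   merge; then closest pairs by Hamming distance merge until at most
   `K_max` (default 40) clusters remain, recomputing each merged
   phenotype from the pooled cells.

Everything non-destructive is tag-based: gates, the downsampled subset,
split halves and final cluster labels are per-event tags, and the events
matrix is never truncated.

## Worked example

The built-in generator creates a two-group, two-batch benchmark with 8
populations of known marker patterns, one of which is group-differential
(30% of cells in group A vs 5% in group B):

```r
library(cytopipe)

design <- benchmark_design(n_samples_per_group = 4, n_events = 5000, seed = 1)
sim <- simulate_dataset(design)
ds <- sim$dataset
ds
#> <cp_dataset> 8 samples, 6 channels, groups: A(4), B(4)

# align the +0.4-unit batch shift on CD3/CD4 (two landmarks per channel)
map <- build_landmark_map(ds, landmark_spec(c(CD3 = 2, CD4 = 2)))
ds <- normalize_dataset(ds, map)

# tag a balanced subset, rescale all channels to [0, 1]
ds <- downsample_balanced(ds, seed = 1)
ds <- rescale(ds)

# embed and cluster
emb <- run_umap(ds, ds$panel$label, seed = 1)
res <- guided_cluster(ds, ds$panel$label, seed = 1, embedding = emb)
res$K_final
#> [1] 8
res$phenotypes$bits
#>   CD3 CD4 CD25 FoxP3 CD127 CTLA4
#> 1   1   1    1     1     0     1
#> 2   1   1    1     1     0     0
#> 3   0   0    1     0     1     1
#> ...
```

The 8 designed populations are recovered with their designed marker
patterns. Per-sample abundances, group statistics and a ROC of the
differential cluster:

```r
ab <- abundance_table(res$dataset)
round(head(ab[, 1:8], 4), 1)
#>        1    2    3    4    5    6    7    8
#> A_1 30.2 10.0 10.0 10.0 10.9  9.2  9.7 10.1
#> A_2 29.9 10.5 10.1 10.8  9.1 10.2  9.6  9.9
#> A_3 30.5  9.9 10.2 10.5  9.9 10.0  9.6  9.4
#> A_4 29.7  9.7  9.7 10.5  9.9 10.6 10.0 10.0

cmp <- group_compare(ab)
head(cmp[order(cmp$p_adj), c("cluster", "median_A", "median_B", "p", "p_adj")], 3)
#>   cluster median_A median_B      p  p_adj
#> 1       1    30.03     5.37 0.0294 0.0304
#> 2       2     9.95    14.12 0.0304 0.0304
#> 3       3    10.04    13.66 0.0304 0.0304

roc_analysis(ab[["1"]], ab$group, positive_group = "A")
#> <cp_roc> positive = A, AUC = 1.0000, Youden cutoff = 29.72
```

Cluster 1 — the designed differential population — sits at ~30% in
group A and ~5% in group B (with only 4 samples per group, the rank-sum
p-value bottoms out near 0.03; the abundance gap itself is the designed
25 percentage points, and it separates the groups perfectly, AUC = 1).
Processed samples can be exported back to FCS with the UMAP coordinates
and cluster IDs appended as extra channels via `write_fcs()`.

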