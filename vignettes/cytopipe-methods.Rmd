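---
title: "cytopipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytopipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cytopipe is a non-interactive, scriptable workflow for flow and mass
cytometry data. It takes a dataset from raw FCS files to cluster
phenotypes, per-sample abundances, group statistics and ROC curves,
with every step driven by code or declarative configuration rather than
point-and-click interaction. This vignette explains the models and
procedures behind each stage, the parameters that matter, and the design
choices that were genuinely open.

## Data model

A `cp_sample` holds one FCS file in memory: an events matrix (rows =
cells, columns = channels), channel metadata keyed by the stable FCS
short name (`$PnN`) with a renameable user-facing label, the TEXT-segment
keywords, and named per-event *tags*. A `cp_dataset` is an ordered set of
samples sharing one panel, with a group per sample.

Two conventions run through the whole package:

* **Nothing is ever deleted.** Gating, downsampling and splitting mark
  events with boolean tags (`gate:<id>`, `downsampled`, `split:A/B`);
  the events matrix never shrinks. Any stage can therefore be re-run or
  audited after the fact.
* **Transformed in place, recoverable by provenance.** Events are stored
  on whichever scale the last operation produced. Each sample carries an
  append-only provenance log (operation, parameters, timestamp), so the
  raw scale is recoverable through the recorded inverse transforms
  rather than by caching a second copy of the data.

Checkpoints (`save_checkpoint()` / `load_checkpoint()`) persist a whole
dataset between stages in a versioned, self-describing container with a
bit-exact round-trip.

## Transformations

Three display transforms are implemented per channel:

* **arcsinh**: \(y = \operatorname{asinh}(a + b x) + c\), closed form in
  both directions.
* **biexponential**: \(y\) solves
  \(x = a e^{b (y - w)} - c e^{-d (y - w)} + f\); the forward map is the
  numerical inverse, found by bracketed bisection to \(10^{-8}\)
  absolute tolerance.
* **logicle**: the Parks–Roederer–Moore biexponential family
  parameterized by top-of-scale `t`, linearization width `w` (decades),
  total display decades `m`, and additional negative decades `a`. The
  inverse (display to signal) is closed form once the family's internal
  coefficients are solved for; the forward map is obtained by vectorized
  bisection on it. Output is scaled to `[0, m]` decades rather than
  `[0, 1]` so transformed values are directly comparable across channels
  before rescaling; with the defaults, signal 0 maps to 0.5 and `t` maps
  to 4.5.

Values below the logicle domain floor are clamped to the transform of
the floor and the clamped-event count is recorded in provenance.
`estimate_logicle()` implements the de-facto standard automatic rule:
`t` from `$PnR` (or the observed maximum), `m = 4.5`, `a = 0`, and
`w = max(0.1, (m - log10(t/|r|))/2)` with `r` the 5th percentile of the
channel's negative events (`w = 1` when there are none).

## Compensation

Spillover is linear in signal, so compensation always operates on the
linear scale: observed events `O` become `O S^{-1}`. When invoked after
transformation, the covered channels are inverse-transformed,
compensated, and re-transformed — the pipeline's canonical order puts
transformation first, and this round-trip keeps the linear algebra
valid. Matrices come either from a single shared `cp_spillover` or
per-sample from each file's `$SPILLOVER`/`SPILL` keyword; mass-cytometry
datasets simply skip the stage. Compensation is not idempotent, so a
provenance check warns when a dataset is compensated twice. Compensated
channels are exactly the matrix's channels — no fuzzy name matching.

## Landmark normalization

Batch effects typically displace the density peaks of a channel (the
negative and positive modes of a marker). Normalization proceeds in
three steps:

1. **Peak detection** (`detect_peaks()`): Gaussian KDE with Silverman's
   rule-of-thumb bandwidth on a 512-point grid over the channel range;
   local maxima with topographic prominence below 5% of the global
   density maximum are discarded; the `L` most prominent survivors are
   kept, sorted by position. Both the bandwidth rule and the prominence
   threshold are deliberate defaults: prominence (rather than raw
   height) suppresses shoulders of a dominant mode without missing a
   genuinely smaller second mode.
2. **Target construction** (`build_landmark_map()`): peaks are matched
   across samples by rank — "low" peaks with "low" peaks, "high" with
   "high" — and the per-rank target is the across-sample **median**,
   robust to one aberrant sample. Samples where detection found fewer
   peaks than expected are excluded from the medians and flagged; a
   manual override file (TSV: sample, channel, rank, position) replaces
   detection for those samples, playing the role of interactive peak
   editing. A channel where more than half the samples need overrides
   aborts with an explicit error.
3. **Warping** (`normalize_dataset()`): each sample's channel is mapped
   by the continuous piecewise-linear function sending its peaks to the
   targets, extrapolating with slope 1 (a pure shift) beyond the
   outermost peaks. With `L = 1` the warp degenerates to a global shift.

The warp is monotone by construction whenever peaks and targets are each
strictly increasing, which guarantees rank preservation within a sample
— a property Gaussian-weighted landmark shifts (the gaussNorm lineage
this stage descends from) do not enforce. That simplification is a
deliberate design choice: what downstream stages need is the alignment
property (same-rank peaks coincide across samples after warping), which
piecewise-linear registration achieves directly, and which the test
suite verifies as cross-sample peak-position standard deviation below
0.05 transformed units under a designed 0.4-unit two-batch shift.

## Gating

Gates of four shapes (rectangle, polygon, quadrant, 1D interval) are
declared numerically — in code or in a YAML file — and arranged in a
tree: each gate's membership is ANDed with its parent's tag, so
iterative strategies compose. Per-sample overrides replace the global
geometry wholesale for samples the shared gate does not fit.

Boundary conventions are fixed, since interactively drawn gates never
define them: rectangles, intervals and quadrants are closed on the
lower/left bound and open on the upper/right bound, so the four quadrant
sub-regions (Q1 `++`, Q2 `-+`, Q3 `--`, Q4 `+-`) partition the parent
population exactly; polygon boundary points count as inside.
Point-in-polygon membership uses even-odd ray casting with an explicit
on-edge test and is validated against an independent scalar oracle on
random 3–12-gons.

## Downsampling, rescaling, splitting

`downsample_balanced()` tags a subset in which every group contributes
equally and every sample of a group contributes equally to its group.
With `m_g` samples per group and `n_s` eligible events per sample, the
shared group quota is \(Q = \min_g (m_g \cdot \min_{s \in g} n_s)\) —
the largest quota satisfying both equality constraints without
replacement — and each sample of group `g` receives `floor(Q / m_g)`
events drawn uniformly without replacement. Draws use per-sample RNG
substreams derived from the dataset seed and a hash of the sample ID, so
adding a sample never perturbs another sample's draw.

`rescale()` maps each channel through clipped percentile min–max
normalization, `(x - p_lo)/(p_hi - p_lo)` clipped to `[0, 1]`, with
percentiles (defaults 0.1 and 99.9) pooled over **all** events of all
samples, downsampled or not. Bounded output stops highly expressed
channels from dominating Euclidean distances purely by magnitude, and
the percentile clip makes the range robust to outliers; z-scoring was
rejected because unbounded tails would reintroduce exactly that
dominance.

`split_dataset()` splits the cells of each sample — never the samples —
into `split:A` (`floor(fraction * n)` events) and `split:B`, within the
downsampled set when one exists, so both halves contain every sample.

## UMAP embedding

`run_umap()` embeds all downsampled events over the stated channels
(uwot backend; defaults `n_neighbors = 15`, `min_dist = 0.1`, Euclidean
metric). It runs single-threaded under a fixed seed: embedding
coordinates are bit-reproducible, trading speed for determinism.

## Guided semi-supervised clustering

The clustering method proceeds in four stages:

1. **Hierarchical training**: a seeded uniform subset
   (`training_fraction`, default 0.1) of the downsampled events is
   clustered agglomeratively — Ward linkage on Euclidean distance over
   the rescaled channels — and the tree is cut into `K_init` (default
   100) fine clusters. Ward on rescaled channels is the configurable
   default because marker-defined populations are compact and roughly
   spherical on that scale; clustering the rescaled (not raw
   transformed) intensities follows directly from why rescaling exists
   at all.
2. **kNN propagation**: every remaining event receives the majority
   label of its `k_nn` (default 11) nearest training events; training
   events keep their own labels. Ties between majority labels fall back
   to the single nearest neighbour's label, making assignment fully
   deterministic. The implementation (a KD-tree search) is tested for
   exact equality against a brute-force all-pairs oracle.
3. **Binarization**: per fine cluster and channel, the fraction of
   member events above the channel's positivity threshold is computed;
   the phenotype bit is 1 iff that fraction exceeds 0.5 strictly.
   Thresholds come from `estimate_thresholds()` — the minimum-density
   valley between the two highest KDE peaks when a pooled channel is
   bimodal, the pooled median otherwise — and any user-supplied cutoff
   wins, so the automatic rule is only a starting point for what is, in
   practice, a judgement call.
4. **Binary-proximity collapsing**: clusters with identical bit vectors
   merge first; then, while more than `K_max` (default 40) remain, the
   pair with the smallest Hamming distance between bit vectors merges,
   with deterministic tie-breaking (pair containing the smallest cluster
   by member count, then lowest original cluster IDs). After every merge
   the phenotype is recomputed from the pooled member events —
   implemented exactly as the size-weighted mean of the member
   fractions, which is algebraically the pooled fraction. Final clusters
   are renumbered by decreasing size.

Recomputing phenotypes from pooled events (rather than freezing the
initial bits) lets a merged cluster change its phenotype and thereby its
future merge partners; stage-1 merges can never flip a bit (a weighted
mean of fractions all above 0.5 stays above 0.5), so the identical-merge
phase is order-independent. Collapsing is idempotent and never increases
the cluster count.

## Reporting

* `phenotype_table()`: per-cluster, per-channel median rescaled
  intensity.
* `abundance_table()`: percent of each sample's clustered events per
  final cluster (rows sum to 100; absent clusters zero-filled).
* `sample_umap()`: UMAP of the *samples* in abundance space, with
  optional metadata joined for colouring and an outlier flag — nearest
  neighbour distance above the median plus 3 MAD. Outliers are flagged,
  never removed; dropping samples is a decision the analyst must make
  explicitly.
* `group_compare()`: per cluster, a two-sided Wilcoxon rank-sum test for
  two groups or Kruskal–Wallis for more, with Benjamini–Hochberg
  adjustment across clusters. Nonparametric tests are the field default
  for cell frequencies, which are bounded, compositional and often
  skewed.
* `roc_analysis()`: the empirical ROC of any per-sample feature, with
  the AUC computed by the rank-based (Mann–Whitney) formulation —
  identical to the trapezoidal area and robust to ties — and the Youden
  cutoff (maximizing sensitivity + specificity − 1, ties resolved to the
  lower cutoff).

## Synthetic data generator

`simulate_dataset()` generates multi-sample, multi-group datasets from
per-group Gaussian-mixture population specs, with optional additive
batch shifts (on the transformed scale — the displacement landmark
normalization corrects) and optional spillover mixing with a
self-contained `$SPILLOVER` keyword (linear-scale mode, for exercising
compensation). Ground-truth population labels are returned in a side
table and never enter the samples the pipeline sees.

`benchmark_design()` is the standard fixture: 8 populations with
distinct 6-bit marker-positivity patterns over 6 channels, negative and
positive modes at 1.0 and 3.0 transformed units with standard deviation
0.15, two groups of 4 samples at 10^4 events each, a +0.4-unit batch
shift on two channels for the second half of each group's replicates,
and one group-differential population (30% of events in group A versus
5% in group B). These defaults emulate a well-behaved two-batch flow
experiment: modes separated by many standard deviations, purely additive
batch effects, no debris, doublets, spectral overlap or
acquisition-time drift. Tests passing on this fixture demonstrate the
pipeline's mechanics — alignment, balance, label recovery, statistical
detection — not robustness to every pathology of real instruments.

## Numerical and testing choices

* Root-finding: logicle internal coefficient by `uniroot` at 1e-14;
  forward transforms by vectorized bisection (80 iterations for
  logicle; bracket-doubling plus bisection to 1e-8 for the
  biexponential).
* Degenerate inputs: constant channels abort rescaling; empty parent
  gates report 0% with a warning; empty clusters are excluded from
  binarization with a warning; samples with zero clustered events are
  excluded from abundance tables with a warning.
* Problem sizes in the validation suite are chosen to finish a full run
  in well under a minute while keeping every check meaningful: 1000-point
  transform grids, 10^5-event compensation recovery, 8 samples x 3000
  events for normalization alignment, 2 x 10^4 cells for the
  end-to-end clustering benchmark, 500/2000 events for the kNN oracle,
  and 5000 + 5000 points for the binormal ROC (where the true AUC is
  \(\Phi(\sqrt 2) \approx 0.921\)).
* The null-calibration check for `group_compare()` permutes group labels
  and compares the exact rank-sum p-values against Uniform(0,1) with a
  Kolmogorov–Smirnov test; it uses 50 samples per group so the discrete
  null support is fine relative to the continuous reference — with
  typical cohort sizes (10 per group) the discreteness of the rank-sum
  distribution would dominate the KS statistic.

## Known limitations

* FCS 2.0 and vendor containers are not read; integer data is supported
  for uniform 16- or 32-bit parameters only; writing always emits
  float32 FCS 3.1.
* Normalization assumes peak-shaped (post-transform) channel densities
  and rank-matchable peaks; it does not model cross-batch anchor samples
  (a shared control sample is treated as just another sample).
* Spectral unmixing, autofluorescence subtraction, automated
  (data-driven) gating, ellipse gates, and density-dependent
  downsampling are out of scope, as are third-party clusterers — the
  guided method is the only one shipped, though ARI comparison against
  any external labelling is straightforward from the returned label
  vectors.
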