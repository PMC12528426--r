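---
title: "Inferring CNAs and clonal origin from single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring CNAs and clonal origin from single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaclone)
```

## The model

A chromosome-arm copy-number change shifts the expression of most genes
on the arm in the same direction, by a roughly constant amount in log
space. Per-gene expression is far too noisy to show this for any single
gene, but averaging over ~100 genome-adjacent genes converts gene-level
noise into a segment-level signal: a cell with a 3p deletion shows a
contiguous block of depressed smoothed values across 3p, while a
diploid cell fluctuates around zero everywhere. `cnaclone` implements
this inference together with the downstream clonal analyses it
supports: subclone detection, neoplastic classification, and the
pre-neoplastic glial calls that identify cells sharing only the
tumour's initiating event.

The assumptions are those of all expression-based CNA inference:

- expression is TPM-like (depth-normalised), so per-cell scaling
  effects are small relative to the +/-0.15 decision band;
- the reference cell types are diploid at essentially every position,
  so their smoothed profiles define the zero envelope;
- arm events are large (tens of genes or more) relative to the
  smoothing window; focal events are invisible by design;
- cell-type-specific transcriptional programs are either absorbed by
  the reference envelope or small after 100-gene smoothing.

## Pipeline stages and their parameters

**Preprocessing.** TPM values are transformed to `log2(TPM/10 + 1)`;
cells need at least 1000 detected genes and a mitochondrial fraction
strictly below 30% (`qc_filter()`); genes are kept when their mean log
value across the analysis matrix strictly exceeds 4.5; each gene is
then mean-centred. Filtering and centering are applied per analysis
matrix (patient cells + reference together), so the reference
participates in every gene's zero point. The 4.5 cutoff is read as a
threshold on the mean of the log-transformed values across cells — the
transform is specified first, and the average is taken "across all
cells" — rather than the log of the mean TPM; the two readings select
similar gene sets at this depth, and the cutoff is a plain argument if
a user prefers the aggregate reading.

**Reference.** From each donor with at least 15 cells of a
presumed-diploid stromal type (fibroblast, endothelial,
adrenocortical), exactly 15 are sampled without replacement
(`build_pooled_reference()`). Equal per-donor draws stop any one
donor's batch from dominating the envelope. Donors and types are
visited in sorted order so a fixed seed reproduces the draw. An
alternate per-patient reference (same-patient stroma plus normal-tissue
glia) is assembled by passing any cell-id/cell-type table as
`reference`; this is the configuration used when glial-specific
programs must not register as events.

**CNA inference** (`infer_cna()`): centred values are clipped to
[-3, 3] (`clip_bound = 3`) so single extreme genes cannot dominate a
window; genes are ordered by chromosome and start (coordinate ties
broken by gene id, for determinism); each cell is smoothed with a
centred moving average of up to 100 genes (`window = 100`). Windows are
truncated at chromosome boundaries and never span chromosomes —
whether the original procedure truncated there is unstated, but
cross-chromosome bleed has no biological reading. For an even window
the extra position is taken downstream (49 left, 50 right). Per
reference type, the mean smoothed profile is computed; at each position
the highest type mean is subtracted from positive values and the lowest
from negative values. A value whose sign would flip is set to 0: a
positive deviation smaller than the reference envelope is no evidence
of amplification. Finally all values strictly inside (-0.15, 0.15) are
set to exactly 0 (`noise_floor = 0.15`); the band is read as open, so
boundary values survive — the choice is immaterial on continuous data
but fixed for reproducibility.

**Subclones** (`detect_subclones()`): positions are ranked by mean
|CNA| across cells and the top 2/3 kept. The reduction is applied to
positions (columns), not cells — every cell must remain clusterable —
and ties keep genome order. Cells are embedded with PCA (10
components), a k = 15 nearest-neighbour graph is built, and Louvain
modularity optimisation over-partitions it; the embedding is an
implementation detail, chosen deterministic, and the contract is the
clone-recovery property, not coordinates. Arm events per cluster are
called on the *full* matrix at |mean| > 0.15, and clusters with
identical event profiles are merged iteratively until all remaining
profiles differ on at least one arm. The cluster count strictly
decreases each round, so the loop terminates within (initial - 1)
rounds.

**Neoplastic classification** (`classify_cells()`): a cell's CNA
signal is the mean |CNA| over its own top 20% of positions by |CNA|
(the "top genes" are read per cell — the metric is defined cell by
cell — with genome-order tie-breaks); the tumour profile averages the
top 20% of candidate cells by signal (ties by cell id); CNA correlation
is Pearson against that profile (rank correlation available via
`method`), with constant vectors returning 0 under a warning. Cutoffs
are median + 2 sample SDs (n-1 denominator, appropriate for small
reference sets) of the reference cells' metrics; malignant means
strictly above both. Correlation uses all positions, not only the
selected top ones, so it remains comparable across cells.

**Glial clonal status** (`classify_glial()`): each glial cell's
arm events (same +/-0.15 rule, per cell) are intersected with the
tumour's event set, matching arm *and* direction. No shared event:
non-neoplastic. All tumour events shared: full match. A nonempty
proper subset — in VHL-mutated tumours, the 3p deletion alone —
pre-neoplastic. Events a glial cell carries that the tumour does not
are ignored by this comparison.

**Differential expression.** `pairwise_de_wilcoxon()` uses the exact
two-sided rank-sum test where R computes it exactly, Bonferroni
adjustment across the genes tested (the genes surviving the 4.5
filter), and log2 fold changes as differences of group means in
`log2(TPM/10 + 1)` space; significance requires adjusted p < 0.05 and
fold change strictly above 0.5. `specific_degs()` intersects the
upregulated lists of all pairwise comparisons involving the focal
cluster. `recurrent_pairwise_de()` uses Welch's t-test (the variant is
unspecified in the source procedure; unequal variances are the safe
default for cells from different tumours), unadjusted p < 0.05 and
|log2FC| >= 1, required against *every* other sample.

## The synthetic cohort

`simulate_expression()` emulates a deep multi-donor Smart-seq2-like
cohort: lognormal gene baselines (log2 mean drawn Normal(5, 2), scaled
by 1.6 so roughly half the genes clear the 4.5 filter, leaving on the
order of 10^3 genes as in a deep single-nucleus matrix), additive
log2-space event shifts applied to carrier cells before
back-transformation, Gaussian log2 noise, a per-cell lognormal depth
factor, and optional Bernoulli dropout. Carrier counts are
`round(fraction x n)` per donor and cell type, and the same spec and
seed reproduce the matrix bit for bit.

Defaults are fixed once as the simulated study conditions:

- `noise_sd = 0.5`: the genes surviving the 4.5 filter are the
  high-expression regime (TPM above ~200), where log-scale residual
  dispersion in deep full-length data is well below 1;
- `depth_sd = 0.05`: TPM units are depth-normalised, so only a small
  per-cell residual remains;
- `dropout_rate = 0`: deep full-length libraries show little dropout
  among highly expressed genes; dropout is an optional stressor;
- `default_genome()`: five chromosomes of two 150-gene arms each —
  arm sizes of the order seen after filtering, with 3p well supported
  relative to the 100-gene window.

The canonical validation cohort (`clone_recovery_cohort()`) raises
`noise_sd` to 1.0 and plants a 0.6 log2 deletion on 3p in 100% of 300
tumour cells and 10% of 200 glia. It also plants a *tumour-private* 1p
deletion: pre-neoplastic status is defined as sharing a proper subset
of the tumour's events, so the category is only non-empty when the
tumour carries at least one event beyond the initiating one — and 1p
loss is itself a recurrent secondary event in these tumours. The
stromal layout (two fibroblast donors, three endothelial, two
adrenocortical, 20 cells each) makes the donor-balanced reference come
out at 30/45/30.

What the simulator does *not* model: transcriptome-wide co-expression
programs, cell-cycle structure, allele-specific expression,
cell-type-specific expression differences between the reference types,
ambient RNA, or doublets. Passing tests therefore show the pipeline's
arithmetic and its recovery behaviour under clean clonal structure;
they do not show robustness to glial transcriptional programs
mimicking deletions, which is exactly why the per-patient reference
mode with normal-tissue glia exists for real data.

## Numerical choices and degenerate inputs

- `window = 1` reduces smoothing to the identity; a single-gene
  chromosome is its own window.
- All-zero CNA matrices are valid everywhere: position selection falls
  back to genome order under total ties, clustering runs on the
  zero embedding, profiles come out all-`none`, and constant-vector
  correlations return 0 with a warning rather than NaN.
- Empty QC results, empty references, empty target selections and
  under-sized groups raise immediate, stage-tagged errors instead of
  propagating empty matrices.
- The moving average is computed by per-chromosome cumulative sums;
  agreement with naive window enumeration is exact up to floating-point
  summation order (~1e-15), which the tests pin at 1e-12.
- Seeds: one global seed fans out to per-stage seeds derived from the
  stage name, so adding a stage does not shift another stage's draws.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
cohorts sized for tight feedback: 1500-gene genomes, 200-640-cell
matrices, 20 replicates for null calibration, and 50 random matrices
for the smoothing oracle. These sizes were chosen so the whole suite
completes in well under a minute while every recovery property is
still comfortably powered; nothing in the implementation depends on
them, and the same code runs unchanged on transcriptome-scale
matrices (the smoothing step is linear in cells x genes).

## Known limitations

- **Arm bleed.** A 100-gene window spans the centromere, so a strong
  event on one arm leaks into the adjacent arm of the same chromosome.
  At the 0.6 log2 effects used throughout, the leaked arm mean stays
  below the 0.15 threshold; at effects near 1 log2 unit it can cross
  it, producing a spurious sibling-arm call — and, downstream, clusters
  of the same clone that refuse to merge because their bleed calls
  straddle the threshold. Interpreting sibling-arm events next to a
  strong event requires care.
- **Per-cell depth residue.** A per-cell constant in log space survives
  gene centering and reference subtraction unchanged; cells whose
  depth residue exceeds the 0.15 band acquire genome-wide spurious
  signal. TPM input keeps this small, but raw counts must not be fed
  in directly.
- **Relative, not absolute.** Values are relative to the reference
  envelope; no absolute copy numbers, no BAF integration, no
  HMM segmentation.
- **Arm events only.** Subclone profiles are defined at chromosome-arm
  resolution; subclones differing only by focal events are merged.
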