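# cnaclone

Copy-number aberration (CNA) inference and clonal-origin classification
for deep single-nucleus RNA-seq of neuroendocrine tumours
(pheochromocytoma / paraganglioma, PPGL) and their microenvironment.

## The problem

Sustentacular (Schwann-cell-like) glia in PPGL are usually regarded as
non-neoplastic stroma. Whether some of them instead share the tumour's
clonal origin can be read from expression data alone: a chromosome-arm
deletion — such as the 3p loss that delivers the *VHL* second hit —
depresses the summed expression of the genes on that arm in every cell
that carries it. `cnaclone` turns a cells-by-genes TPM matrix with
donor and cell-type labels into:

1. **per-cell relative CNA profiles**, by smoothing genome-ordered,
   mean-centred log expression and calibrating against a donor-balanced
   pooled stromal reference;
2. **genetic subclones**, by overclustering cells on their CNA profiles
   and merging clusters until each surviving cluster has a unique
   chromosome-arm event profile;
3. **neoplastic cell calls**, from CNA-signal and CNA-correlation
   cutoffs set at median + 2 SD of the reference cells;
4. **glial clonal status** — non-neoplastic, pre-neoplastic (sharing
   the initiating event only) or full match — by comparing each glial
   cell's arm events with the tumour's;
5. the accompanying **differential-expression procedures** (pairwise
   Wilcoxon intersection markers; recurrent sample-vs-each-other-sample
   t-tests).

A seeded synthetic-cohort simulator plants arm-level events with known
carriers, so every stage can be validated against ground truth.

## The method

For an analysis matrix holding one patient's neuroendocrine and Schwann
cells plus the pooled reference, with TPM values transformed to
`log2(TPM/10 + 1)`, genes with mean log expression > 4.5 kept and
mean-centred per gene:

- centred values are clipped to [-3, 3], genes ordered by chromosomal
  position, and each cell smoothed with a centred moving average of up
  to 100 genes (truncated at chromosome boundaries);
- at each position the highest per-reference-type mean profile is
  subtracted from positive values and the lowest from negative values
  (sign flips are zeroed), and values inside (-0.15, 0.15) are set to
  exactly 0;
- arm events are called where a cluster's (or cell's) mean CNA on an
  arm is < -0.15 (deletion) or > 0.15 (amplification);
- a cell's *CNA signal* is the mean |CNA| over its top 20% positions by
  |CNA|, its *CNA correlation* the Pearson correlation with the average
  profile of the top 20% of candidate tumour cells by signal; cells
  strictly above both median + 2 SD reference cutoffs are malignant.

## Worked example

Simulate the canonical VHL-like cohort — 300 tumour cells and 200 glia
on donor D1, stromal cells across three donors, a 3p deletion (0.6 log2
units) in all tumour cells and 10% of glia, plus a tumour-private 1p
deletion — and run the whole pipeline:

```r
library(cnaclone)

spec <- clone_recovery_cohort(seed = 1)
sim  <- simulate_expression(spec)
sim$expr
#> <expr_matrix> 640 cells x 1500 genes, space = 'raw'

bundle <- run_pipeline(sim$expr, sim$meta, spec$genome,
                       config = pipeline_config(seed = 1), patients = "D1")
reference_composition(bundle$reference)
#> # A tibble: 3 × 2
#>   cell_type      cells
#>   <chr>          <int>
#> 1 adrenocortical    30
#> 2 endothelial       45
#> 3 fibroblast        30

res <- bundle$results$D1
res$subclones
#> <subclone_result> 300 cells, 1 cluster(s) after 1 merge round(s) (from 5)
#>   cluster 1: 1p del, 3p del

res$classification
#> <cna_classification> 605 cells (105 reference); 307 malignant
#>   cutoffs: signal > 0.275, correlation > 0.357

table(res$glial$glial_status)
#> non_neoplastic pre_neoplastic
#>            173             27
```

The donor-balanced reference holds 30 + 45 + 30 stromal cells (15 per
qualifying donor and type). The tumour cells collapse into a single
subclone carrying both planted deletions; 307 of 605 cells pass both
neoplastic cutoffs (the 300 tumour cells, essentially); and 27 glial
cells — the 20 planted 3p carriers plus a few borderline cells — are
pre-neoplastic: they share the tumour's 3p deletion but not its 1p
deletion. Results tidy into tibbles (`tidy()`, `glance()`) and plot
with `autoplot()` (CNA heatmap, signal-vs-correlation scatter).

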