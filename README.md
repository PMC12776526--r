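# cytodict

Analysis toolkit for **multi-donor cytokine stimulation screens** of
PBMCs profiled by single-cell RNA sequencing. Screens of this design
stimulate cells from a dozen donors with a library of cytokines (plus
six PBS control wells per donor plate) and ask, per cell type: which
genes respond, how strongly and how specifically, how consistent the
response is across donors and control wells, which cell types
communicate through which cytokines, and whether the resulting
signatures can be detected in new datasets.

`cytodict` implements that pipeline end to end:

* **Pseudobulk differential expression** with a donor-adjusted linear
  model on log2(cpm+1) (equivalent to the paired t-test across donors)
  and two plate-artifact defences: per-PBS-well support counting
  (a DEG must hold against ≥ 4 of 6 control wells at padj < 0.1,
  |log2FC| > 0.25) and a mean-to-stddev ratio filter
  `sd(w)/(|mean(w)|+0.25) > 1` with escalation across cytokines and
  cell types. DEG rule: padj < 0.05, |log2FC| > 0.25, ≥ 4/6 wells.
* **Response magnitude** `M` = mean of two winsorized, [0,1]-normalized
  components — the Euclidean log-expression distance to PBS and
  `Σ|log2FC|·(−log10 padj)` (padj clipped at 1e−10) — with a
  strong-impact threshold `T = 3 × mean(M below the 35th percentile)`
  per cell type and a tissue-specificity index
  `tsi = Σᵢ (1 − max(Mᵢ−Tᵢ/2, .05)/max(M_max−T*/2, .05)) / (N−1)`.
* **Donor heterogeneity**: baseline log2FC vs the cross-donor median,
  per-donor magnitudes and raw strength, outlier detection by
  `|r − top8median| > 0.35·max(top8median, 0.6)`, and donor
  substructure via Leiden/CPM at resolutions 0.3/0.5/0.7 with size and
  margin gates.
* **Communication networks**: receptor logic (min over subunits, max
  over alternative receptors), primary/secondary target
  classification at the 16/5/32 cpm bands, sender×receiver interaction
  scores, cytokine-cytokine regulation counts, and secondary-response
  inference through produced cytokines.
* **Response-similarity grouping**: per-cell-type Leiden/CPM
  communities of strong-impact cytokines, cross-cell-type consensus
  clustering of co-clustering counts, and transitive highly-similar
  groups (≥ 3 shared strong cell types, mean r > 0.7).
* **Cytokine-induced program calls** from externally supplied latent
  factor scores (Bonferroni p < 0.001 in ≥ 4/6 wells, |Δ| ≥ 0.1, ≥ 4
  donors, vote margin ≥ 4).
* **Preranked permutation enrichment** (`δ = (mₐ−m_b)/(σₐ+σ_b)`,
  running-sum ES, permutation null, NES) with a 5×5
  hyperparameter-grid robustness vote and differential cell-cell
  communication inference, including a small-panel (spatial) mode.
* A **synthetic-data generator** that emulates the full plate design
  (12 donors × 12 cell types × cytokines + 6 PBS wells,
  negative-binomial counts, receptor gating, donor groups, plate
  artifacts, secondary cascades) with planted ground truth, so every
  stage has a recovery test without any download.

## Worked example

Simulate a small screen with two planted responses and run the core
stages:

```r
library(cytodict)

cfg <- sim_config(
  n_donors = 12, n_celltypes = 3, cytokines = paste0("CK", 1:6),
  n_genes = 200, cells_per_group = 20,
  effects = list(
    list(cytokine = "CK1", genes = sprintf("G%03d", 1:10), lfc = 2),
    list(cytokine = "CK2", genes = sprintf("G%03d", 11:20), lfc = -2)),
  seed = 1)
sim <- simulate_screen(cfg)
sim$cells
#> CellCounts: 8633 cells x 200 genes
#>   donors: 12 | cell types: 3 | conditions: 7

pb  <- pseudobulk(sim$cells)      # per (donor, cell type, condition/well)
det <- de_table(pb)               # consensus DE + well support + filters
degs <- deg_sets(det)
table(degs$cytokine, degs$direction)
#>       down up
#>   CK1    0 30
#>   CK2   30  0
```

The 10 planted genes per cytokine are recovered in all 3 cell types
(30 calls each), in the planted directions. Magnitudes and specificity:

```r
mag <- magnitude_table(pb, det)
subset(mag$table, cell_type == "CT01",
       select = c(cytokine, M, threshold, strong_impact))
#>   cytokine      M threshold strong_impact
#> 1      CK1 1.0000     0.237          TRUE
#> 2      CK2 0.7893     0.237          TRUE
#> 3      CK3 0.0762     0.237         FALSE
#> ...
round(mag$tsi, 2)
#>  CK1  CK2  CK3  CK4  CK5  CK6
#> 0.02 0.10   NA   NA   NA   NA
```

Only the perturbed cytokines exceed the strong-impact threshold; their
tissue-specificity index is near 0 because the planted response hits
all three cell types uniformly (unperturbed cytokines have no strong
cell type, so tsi is undefined). Recovery against the planted truth:

```r
recovery_metrics(sim$truth$degs, degs,
                 by = c("cell_type", "cytokine", "gene"))
#> precision 1.00, recall 1.00
```

Downstream stages follow the same pattern: `donor_profile()` for
outliers and substructure, `receptor_expression()` /
`classify_targets()` / `communication_edges()` / `infer_secondary()`
for the network, `similarity_matrix()` / `leiden_groups()` /
`consensus_groups()` for grouping, `call_cips()` for program calls,
and `delta_rank()` / `permutation_null()` / `grid_robustness()` /
`differential_communication()` for querying new datasets.
`run_pipeline(run_config(...))` wires the stages over an on-disk count
triplet and writes TSV artifacts plus a manifest.

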