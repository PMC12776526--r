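---
title: "Models and methods behind cytodict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytodict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodict)
```

# The problem

Cytokine stimulation screens expose peripheral blood mononuclear cells
(PBMCs) from a panel of donors to a library of cytokines, with six
unstimulated (PBS) control wells per donor plate, and read out the
response of every cell type by single-cell RNA sequencing. The analysis
questions are always the same: which genes respond in which cell type,
how large and how cell-type-specific each response is, how consistent
responses are across donors and control wells, which cell types talk to
which through which cytokines, and whether those response signatures
can be detected in new datasets. `cytodict` implements that pipeline as
composable, tested functions, together with a synthetic-data generator
that plants known effects so that every stage has a recovery test.

# Data model

Counts enter as a sparse cells-by-genes integer matrix with per-cell
donor, cell type, condition, PBS-well and plate-row labels
(`CellCounts`), read from the Matrix-Market triplet layout written by
combinatorial-barcoding pipelines. All inference happens on
**pseudobulks**: per (donor, cell type, condition) summed counts, with
the six PBS wells kept apart so each well can serve as its own
reference (`pseudobulk()`). Expression is compared on
`log2(cpm + 1)`, cpm being counts per million within each pseudobulk.

Quality control keeps cells with 400–7000 detected genes and strictly
less than 15% mitochondrial content. Doublet removal and clustering are
upstream concerns and are not reimplemented here; cell-type labels are
taken as given.

# Differential expression and its robustness filters

The consensus contrast per (cell type, cytokine) is a linear model on
per-donor pseudobulk `log2(cpm + 1)` with donor indicator covariates
and a condition coefficient. With exactly one PBS and one stimulated
pseudobulk per donor this is algebraically the paired t-test on
per-donor differences, and that is how it is computed (vectorised over
genes, residual degrees of freedom = donors − 1). We chose this backend
because it is exactly testable against closed-form oracles and because
everything downstream consumes only (log2FC, adjusted p); a validated
adapter (`de_external()`) ingests tables from negative-binomial GLM
tools for parity runs, and the test suite cross-checks the backend
against edgeR's quasi-likelihood route on simulated data. Donors enter
a contrast only when both of their pseudobulks contain at least 10
cells; genes only when detected in at least 5% of the retained cells of
either condition (the filter is applied after donor exclusion, on the
retained donors' cells, since those are the cells the model actually
sees).

Two robustness mechanisms target plate artifacts:

* **Per-well support.** The contrast is re-run six times, each with a
  single PBS well as reference; a well supports a gene when that run
  gives adjusted p < 0.1 and |log2FC| > 0.25. Biology is expected to be
  supported by most wells, well-position artifacts are not.
* **Mean-to-stddev ratio.** Per gene and condition,
  `sd(per-well log2FC) / (|mean| + 0.25)` (sample standard deviation;
  the n−1 convention is used, as the six wells are a sample of possible
  references). Ratios above 1 mark instability; genes unstable in ≥ 10
  cytokines of a cell type and in ≥ 5 cell types are removed entirely.

A gene is a DEG when adjusted p < 0.05, |log2FC| > 0.25, at least 4 of
6 wells support it, and the ratio filter has not removed it. When fewer
than six wells exist the well quorum scales as
`ceiling(4/6 × available)` and the result is flagged.

# Response magnitude, strong impact, and specificity

Two complementary scalars summarise a (cell type, cytokine) response:
the Euclidean distance between PBS and cytokine `log2(cpm + 1)`
pseudobulk vectors over genes with an average pseudobulk count of at
least 20 in some condition, and the significance-weighted sum
`Σ |log2FC| · (−log10 padj)` with padj clipped at 1e−10. The |·| on the
fold change keeps every contribution non-negative, as a distance must
be. Each component is winsorized at its 95th percentile (upper tail
only — the low tail carries no outlier risk) using the linear
interpolation quantile (R type 7), rescaled to [0, 1] by its post-clip
maximum, and averaged into the overall magnitude `M`.

The strong-impact threshold per cell type is `T = 3 × mean{M below the
35th percentile}` — an empirical floor on the no-effect part of the
distribution that assumes nothing about its shape, but does assume the
screen contains many weak responses per cell type. That assumption is
real: in a panel where every cytokine hits every cell type the low
tail is itself large and nothing is called strong. Simulated screens
therefore include null cytokines, as real screens effectively do.

The tissue-specificity index of a cytokine over N cell types is

$$\mathrm{tsi} = \frac{1}{N-1}\sum_i \left(1 -
\frac{\max(M_i - T_i/2,\ 0.05)}{\max(M_{\max} - T^*/2,\ 0.05)}\right)$$

where `T*` is the threshold of the cell type attaining the maximal
magnitude — the printed form of the denominator is ambiguous about
which cell type's threshold is meant, and using the maximising cell
type's own threshold keeps the leading term exactly zero; the choice is
exposed as an argument. Subtracting half the threshold suppresses
noise, the 0.05 floor keeps ratios defined, and tsi is reported only
when at least one cell type is strong (NA otherwise). 0 means a uniform
response, values near 1 a single-cell-type response.

# Donor heterogeneity

Donor baseline state is profiled on PBS pseudobulks as
`log2((cpm_d + 1)/(median cpm + 1))` against the cross-donor median,
restricted to protein-coding, non-ribosomal, non-mitochondrial,
non-sex-chromosome genes with ≥ 10 raw reads. Donor responses are
summarised by a per-donor Euclidean magnitude (normalised by the square
root of the gene-vector length, requiring ≥ 1000 filter-passing genes)
and a raw strength `Σ (2^{max(|log2 FC| − 0.5, 0)} − 1)` whose 0.5
deadband discounts single-donor pseudocount noise. Donor fold changes
use a +1 cpm pseudocount on both sides and require ≥ 20 cells in the
stimulated condition.

Outliers: with `r` the Pearson correlation of each donor's log2FC
vector to the consensus and `m` the median of the top 8 values, a donor
is an outlier iff `|r − m| > 0.35 · max(m, 0.6)`. Ties in the top 8 are
resolved by a stable sort on donor id. Substructure: Leiden communities
(CPM objective) on the donor-donor correlation matrix at resolutions
0.3, 0.5, 0.7 taken in ascending order; success needs one community of
size ≥ 4, a second of size ≥ 2, and every qualifying pair to separate
by `max(0.2, 0.3 × max off-diagonal r)` in mean within- minus
between-community correlation. When more than two communities qualify
we require the margin for every pair, the strictest reading of the
rule. Correlations can be negative but the CPM partition assumes
non-negative weights, so edges are floored at zero before clustering;
the Leiden refinement is run under a fixed, exposed seed.

# Communication networks

Receptor expression per (cytokine, cell type) on PBS pseudobulks is the
minimum cpm across a receptor's subunits (all subunits must be present)
and the maximum across alternative receptors (any receptor suffices).
Around the empirical ~8 cpm response threshold, responses classify as
`primary_target` (receptor > 16 cpm, M > 1.5 T), `secondary_candidate`
(receptor < 5 cpm yet M > 1.5 T), `weak_despite_receptor` (> 32 cpm but
M < T), else unclassified. A cytokine is expressed in a cell type when
its encoding genes (minimum across subunits) reach mean cpm > 4, max
cpm > 4 and ≥ 20 counts in some condition. Communication edges require
expression in the sender and strong impact on the receiver; the
interaction score is relative sender expression (gated at mean
cpm > 10 somewhere) times the receiver's normalized magnitude, pruned
at 0.25 for display-oriented lists. Cytokine-cytokine regulation is
called at padj < 0.05 and |log2FC| > 1 with all subunits required, and
netted per family relative to the family's maximal count. Secondary
responses are inferred when a responding cell type lacks the primary
cytokine's receptor, some primary-target cell type upregulates a
candidate secondary cytokine (log2FC > 1), the responder is a primary
target of that cytokine when applied directly, and the two response
profiles correlate with r > 0.5.

# Similarity grouping

Within a cell type, cytokine responses are compared by Pearson
correlation of consensus log2FCs over robustly expressed genes (max
cpm ≥ 20, mean cpm ≥ 4, max pseudobulk count ≥ 20 across conditions; we
read the printed "maximum expression of 20 cpm" as a lower bound, the
only reading consistent with the other two clauses, and keep it
configurable). Strong-impact cytokines are clustered by Leiden CPM at
resolution 0.5 on the zero-diagonal similarity matrix. Consensus
communities across cell types cluster the co-clustering count matrix
(cytokines participating in ≥ 2 cell types), symmetrically normalised
by inverse square roots of row sums (ε = 1e−9), compared by cosine
distance, converted to a similarity as 1 − distance for the weighted
graph. Highly similar groups are the transitive closure of pairs
sharing ≥ 3 strong cell types with mean r > 0.7, averaged over exactly
the shared-strong set.

# Cytokine-induced programs

Latent gene programs arrive as per-cell factor scores plus per-gene
interpretability scores from a disentangling autoencoder trained
elsewhere; training is an input contract, not part of this package.
Factors are retained when |z| > 1 in at least one cell and some gene
has interpretability ≥ 0.5. Program activity for a contrast is
`Δ = (mean z stimulated − mean z in PBS well w) / max over stimulations
of the group mean z`; the printed denominator can be negative for
all-negative factors, so an absolute-value variant exists behind a flag
that defaults off, and affected contrasts are surfaced rather than
silently rescaled. Calling uses Welch t-tests (the paper says only
"t-tests"; unequal variances between stimulated and control wells are
the safe default) of cell-level z against each of the six PBS wells,
Bonferroni-corrected across programs within the (cell type, cytokine)
condition; a donor passes with ≥ 4 of 6 wells jointly at corrected
p < 0.001 and |Δ| ≥ 0.1 (we require the joint per-well pass, the
stricter of the two readings), and a program is called when ≥ 4 donors
pass and the up-vs-down vote differs by ≥ 4.

# Enrichment engine

For a query contrast the per-gene statistic is
`δ = (m_a − m_b)/(σ_a + σ_b)` with an ε-guard of 1e−9, ranked
descending with ties broken by gene id. The running-sum enrichment
score increments on gene-set hits proportionally to |δ|^w (w = 1 by
default, matching the weighted preranked implementations in common use;
w = 0 is available and is what the exhaustive oracle tests exercise)
normalised to +1 total, decrements uniformly to −1 total, and reports
the signed extremum. Significance comes from random gene sets of the
same size (20,000 by default; tests and the acceptance script use
smaller counts suited to their problem sizes), with
`p = (1 + #{|ES_0| ≥ |ES|})/(n+1)` — two-sided on magnitude since the
direction of enrichment is a separate question, with a one-sided option
— and `NES = ES / mean |ES_0|` over null scores of matching sign (the
printed "normalized by the mean of this null distribution" is ambiguous
for signed scores; the plain mean is available).

Robustness re-derives the gene set over five |log2FC| thresholds
(0.8–1.2) crossed with five expression cutoffs (6–10 cpm, integer grid;
program sets use the cpm axis only), skips cells whose set falls
outside 8–1000 genes, and votes: ≥ 1/3 of cells valid, ≥ 2/3 of valid
cells with p < 0.1, all significant cells agreeing in sign. Small-panel
(spatial) mode additionally requires ≥ 10% of the signature to overlap
the panel and raises the validity quota to 1/2. Differential
communication combines verdicts with expression gates: senders by
one-vs-rest Wilcoxon on production-gene cpm (BH p < 0.1, positive
log2FC, mean > 10 cpm), receivers by an "up" verdict plus mean receptor
expression > 10 cpm, gated on the least-expressed subunit for
multimeric receptors.

# The synthetic-data generator

`sim_config()` / `simulate_screen()` emulate one donor cohort: 12
donors, 12 cell types, a cytokine panel plus six PBS wells per donor,
negative-binomial counts (the standard scRNA-seq count model; the
data-generating process is our choice since no generative model is
prescribed) with per-gene lognormal baselines, mild cell-type
variation, lognormal cell depths around 5,000 UMIs, and two dispersion
classes (0.2 housekeeping, 0.4 responsive). Planted effects multiply
expected cpm by `2^lfc` and are returned as ground truth; responses can
be receptor-gated, donor-restricted, or cascaded through a produced
secondary cytokine. PBS wells carry multiplicative lognormal
plate artifacts per (well, gene), shared across donors because the
per-well robustness analysis pools a well index across donors — that is
exactly the failure mode the filter targets. Planted response genes are
pinned to a moderate 300 cpm baseline so a handful of strong effects
does not shift the cpm composition of the rest of the panel, and
cytokine-encoding genes to 20 cpm so production responses clear the
detection filter without dominating.

What the generator does **not** emulate: transcriptome-wide correlation
structure, ambient RNA, cell-type misannotation, batch chemistry
effects, or the tens of thousands of genes of a real panel. Passing
recovery tests therefore demonstrate that the implementations apply
their stated rules correctly and recover effects under the model's own
assumptions — not that those rules are optimal on real data.

# Problem sizes and numerical choices

Tests and the acceptance script run screens of 8–12 donors, 1–4 cell
types, 1–15 cytokines and 100–200 genes with 10–35 cells per (donor,
cell type, well) — large enough for every rule to bind (six wells,
twelve donors, null tails for the threshold rule) while keeping a full
suite in the order of a minute. Percentiles use R's default type-7
linear interpolation throughout. Leiden runs under fixed seeds through
a wrapper that restores the caller's RNG state. p-values are floored at
the smallest positive double rather than reported as zero. Degenerate
inputs follow the module contracts: empty gene sets error or return NA
with a log entry, all-zero magnitude components normalise to zero with
a warning, and missing wells scale well quorums proportionally with a
flag.

# Known limitations

The default DE backend models log-cpm, not counts; very low-count genes
show the usual concavity shrinkage of log-pseudocount estimates (the
cross-check against a count-model route bounds the discrepancy in the
tests). HDF5 single-cell containers are not read — input is the MTX
triplet or in-memory objects. The mean-to-stddev escalation thresholds
(10 cytokines, 5 cell types) only bind on panels at least that large.
Abundance testing normalises plate-row effects with a single linear
fit of well totals on distance to the centre row, the simplest form
consistent with its description, and uses the mean of a donor's PBS
wells as that donor's reference so that one well and six wells are on
the same scale.
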