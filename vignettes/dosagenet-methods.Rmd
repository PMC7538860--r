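---
title: "Methods: QC, communication and dosage-enrichment analysis of snRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC, communication and dosage-enrichment analysis of snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`dosagenet`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data tests do and do not establish about
real data.

## Quality control

Three filters run in a fixed order on a raw gene × cell UMI matrix:

1. **Gene prevalence.** A gene is *detected* in a cell iff its raw count is
   greater than zero (the conventional definition; counts are UMI, so a
   single molecule counts as detection). Gene `g` is kept iff it is
   detected in at least `min_gene_prevalence × n_cells` cells
   (default 0.001, i.e. 0.1% of cells; the comparison is `>=`, so with
   2,000 cells a gene seen in exactly 2 cells survives).
2. **Mitochondrial fraction.** A cell fails iff
   (mito UMI)/(total UMI) is *strictly greater* than `max_mito_fraction`
   (default 0.10). High mitochondrial content in nuclear preparations
   marks lysed or debris-laden droplets. Zero-total cells get fraction 0
   and a degeneracy flag rather than NaN.
3. **UMI window.** With Q1 and Q3 the quartiles of per-cell totals and
   IQR = Q3 − Q1, cells are kept iff their total lies in the closed
   interval `[Q1 − k·IQR, Q3 + k·IQR]` (default `k = 1`). Quartiles use
   linear interpolation between order statistics (`quantile(type = 7)`);
   this convention is pinned because the quartile method changes the
   retained set. The window is computed on the cells that survived the
   mito filter, mirroring the enumerated order of the filters; computing
   it on all cells instead is exposed as `bounds_on_all_cells` because
   with a heavy debris load the two choices differ.

The housekeeping check is deliberately *advisory*: it reports the fraction
of a supplied housekeeping-symbol list detected in at least 50% of the
retained cells (the 50% cut is this package's definition, recorded in the
report), and never removes anything — it verifies reliability rather than
filtering.

Two properties worth knowing. First, the pipeline is *not idempotent*:
re-running QC on already-filtered cells recomputes a narrower IQR and can
shave a further small fraction (< 5% at the defaults; tested). Second, the
one-IQR window is intrinsically aggressive on right-skewed library-size
distributions: with per-cell library factors lognormal(σ = 0.3) — a
realistic droplet spread — the upper tail alone places ≈ 5% of perfectly
good cells outside `Q3 + IQR`. This is a property of the rule, not a bug;
the QC tests therefore expect ~5% clean-cell loss alongside ≥ 90% debris
removal.

## Cell-cycle scoring and phase assignment

Expression is library-size normalized (each cell scaled to a total of
10,000, then `log(1 + x)`) before scoring; raw-count module scores would be
dominated by sequencing depth.

The S and G2/M program scores use the standard expression-bin control:
all genes are ranked by mean normalized expression across cells and split
into `n_bins = 25` equal-frequency bins; for each program gene, `n_ctrl =
50` control genes are sampled (seeded; without replacement when the bin is
large enough) from the gene's own bin; the score is the mean over program
genes minus the mean over the pooled control draw. Bin-matching removes
the mean-expression confound, so a program of highly expressed genes does
not score high merely for being highly expressed. On a matrix where every
gene is constant and equal the score is exactly 0, and a random gene set
scores within ±0.05 of 0 on hundreds of cells — both tested.

Phases follow the explicit rule set: a cell is quiescent (**G1**) iff its
S score < 0 *and* its G2/M score < 0; otherwise it is proliferative and is
called **G2M** when the G2/M score exceeds the S score and **S** when the
S score exceeds the G2/M score. The measure-zero tie (equal, non-negative
scores) goes to G2M because the G2/M comparison is stated first; the
tie-break is a documented argument. With arbitrary (e.g. random) gene
sets roughly half of null scores are non-negative, so the proliferative
fraction on unstructured data is large — phase calls are only as
meaningful as the gene sets. The package ships the widely used human
S (43 genes) and G2/M (54 genes) lists in
`inst/extdata/cell_cycle_human.gmt` as a convenience default and treats
gene sets strictly as inputs.

## Cluster profiles and the marker ranking

Per-cluster mean expression is computed on **raw UMI** — the communication
threshold downstream is stated in UMI units, so the means must stay in
those units. Marker testing, by contrast, runs on log-normalized values:
a one-vs-rest two-sided Wilcoxon rank-sum per gene, implemented as the
tie-corrected normal approximation without continuity correction. Gene
ranks are computed once and per-cluster rank sums are a single matrix
product, which makes the 200-repetition null calibration (below) cheap;
the implementation is verified against `stats::wilcox.test(exact = FALSE,
correct = FALSE)` to 1e−10. Fold changes are
`log2((mean_in + 1)/(mean_out + 1))` on raw cluster means — the
pseudocount of 1 avoids division by zero and damps fold changes of barely
expressed genes. BH adjustment is applied within cluster; markers are
genes with adjusted p < 0.05 and log2 fold change > 0.25, ranked by fold
change. Singleton clusters are skipped with a warning (a rank-sum against
one observation is meaningless).

## The communication network

A molecule is *expressed* in a cluster iff its cluster-mean UMI is
**strictly greater than 1**. "Above a threshold of 1" is ambiguous at
exactly 1.0; strict comparison was chosen and the boundary semantics are
exposed (`inclusive = TRUE`) so the other reading costs one flag. For
every pair (L, R) in the curated table and every *ordered* cluster pair
(a, b) — including a = b, since within-cluster signalling is part of the
network — an edge (a, b, L, R) is emitted iff L is expressed in a and R in
b. A gene annotated as both ligand and receptor is counted in both roles
and reported as such. Anatomical plausibility is deliberately ignored:
the network is a co-expression statement, not a spatial one. Pair symbols
missing from the gene universe are skipped and reported rather than
failing the run. The summary matrix (rows = sources) is exactly the
chord-diagram input; rendering is left to external tools.

No permutation-based significance is attached to edges (CellPhoneDB-style
testing is a different method); edges here are threshold statements.

## Hypergeometric panel enrichment

For a cluster with n markers, a panel with K members inside the universe
of N genes, and k overlap, the reported p is the upper tail
P(X ≥ k) = Σ_{i=k}^{min(n,K)} C(K,i)·C(N−K,n−i)/C(N,n), evaluated via
`phyper` (log-space internally). The tests pin this down two independent
ways: exact enumeration from binomial coefficients on every instance with
N ≤ 12, and Monte-Carlo frequencies from 10⁶ hypergeometric draws on
random larger instances within three standard errors.

The **universe is the set of genes that survived QC**, not the genome:
markers can only be drawn from tested genes, and an inflated universe
would manufacture enrichment. BH adjustment is applied jointly across all
cluster × panel tests; the raw p is also reported since some analyses
correct per panel. The chromosome-21 panel is built from the annotation
table (labels `chr21`/`21`, case-insensitive); disease panels come from
GMT files. The shipped `retinal_disease_panels.gmt` carries only the
handful of marquee genes (RPE65, OTX2, LRAT, BEST1; NR2F1, AFG3L2) and is
intended for smoke tests, not for real inference.

## The pooled correlation network

Within each cluster, cells are shuffled with a seeded RNG and partitioned
into consecutive pools of 30; the remainder is dropped rather than forming
a short pool, keeping pool variance homogeneous (the grouping rule behind
"every 30 cells" is otherwise unspecified, so a seeded random partition is
pinned). Pool profiles average **log-normalized** expression — raw-UMI
correlations are driven by library size — with raw averaging available as
a flag. All unordered pool pairs are scored with Pearson r and edges keep
r > 0.95 (strict).

On the synthetic defaults the within-cluster median r (≈ 0.40) clearly
exceeds the between-cluster median (≈ 0.19), but almost no pair crosses
0.95: the generator's flat baseline (a single mean for all background
genes) leaves little shared gene-level variation for pools to agree on.
Real transcriptomes have per-gene means spanning orders of magnitude,
which pushes same-type pool correlations toward 1; the 0.95 default is
kept because it is the method's operating point on real data, and the
tests assert the ordering (within > between), which is the property the
synthetic conditions can support.

## The synthetic-data generator

The generator emulates the downstream-visible structure of a droplet
snRNA-seq experiment on a trisomic tissue at desk scale:

- 10 clusters × 300 cells, 2,000 genes (defaults; a few hundred cells per
  cluster matches the scale of a single-donor fetal-retina run).
- Counts are negative binomial with gene-level mean 0.5 UMI and dispersion
  (size) 2 — nuclear libraries are shallow, and size 2 gives the
  overdispersion single-cell counts show; as size → ∞ the generator
  provably approaches Poisson (tested).
- 13 mitochondrial genes (the human chrM protein-coding count) at 5× the
  baseline mean, putting clean-cell mito fractions near 3%.
- Per-cell library factors lognormal(0, σ = 0.3), giving the IQR filter a
  realistic spread to act on.
- 2% debris cells: mito means ×10 and library ×0.2, the canonical lysed
  profile, giving the mito and UMI filters true positives.
- 2% of genes labelled chr21 (≈ chr21's share of coding genes), assigned
  deterministically to the lexicographically first non-mito symbols; a
  designated cluster can have those genes' means multiplied by
  `dosage_fold` (2 in the recovery tests — a trisomy is a 1.5× copy
  change, and 2× keeps the desk-scale test decisive while staying in the
  biologically discussed range).
- 20 marker genes per cluster at 4× baseline, giving the rank-sum ranker
  something unambiguous to find.
- Five planted ligand–receptor pairs (C0→C1 … C8→C9) whose planted mean
  of 5 UMI clears the expression threshold of 1 with margin.

A single RNG stream keyed by the seed is consumed in a documented order
(library factors, debris selection, count draws), so identical
configurations are byte-identical. The gene annotation table is
RNG-free.

What the generator does **not** model: ambient RNA, doublets, batch
effects, gene–gene correlation beyond the planted programs, realistic
mean–variance trends across genes, or any actual retinal biology. Passing
recovery tests therefore demonstrates that the implementations detect the
structures they are defined over — not that the methods are powerful or
calibrated on real tissue.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes simulate (optional) → qc → cellcycle → profile →
markers → commnet → enrich → corrnet, writing per-stage tables and a JSON
manifest with an MD5 for every file. One explicit master seed fans out to
stage seeds by the fixed derivation `seed × 97 + stage_index`, so any
stage can be reproduced in isolation; outputs carry no timestamps, making
reruns byte-identical (asserted by checksum in the tests).

Problem sizes used by the test suite and the acceptance script, chosen to
keep a full run on one CPU in a few minutes: unit tests run 3–5 clusters
of 60–150 cells with 200–400 genes; recovery checks run the full default
configuration (3,000 cells × 2,000 genes) across 10–20 seeds; the null
calibration runs 200 label permutations on one default-size dataset
(the rank matrix is computed once, so each permutation costs one matrix
product); pipeline determinism is checked at the full default size.

## Known limitations

- The marker ranker uses the normal approximation throughout; for
  clusters of fewer than ~10 cells exact Wilcoxon p values would differ.
- Enrichment treats marker lists as fixed sets; uncertainty in marker
  selection is not propagated (the null calibration shows the combined
  pipeline is conservative, rejecting far below nominal under shuffled
  labels, because BH-thresholded marker lists are usually empty under the
  null).
- The communication network has no significance model, by design.
- Phase assignment is only as good as the supplied S/G2M sets; the
  shipped lists are human-centric.
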