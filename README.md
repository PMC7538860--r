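# dosagenet

Downstream analysis of droplet single-nucleus RNA-seq (snRNA-seq) count
matrices, built around the question of chromosome-dosage effects — the kind
of analysis used to ask whether an aneuploid tissue (e.g. a trisomy-21
retina) shows cell-type-specific over-representation of genes from the
extra chromosome, and how its cell populations signal to each other.

The package is aimed at analysts who already have a gene × cell UMI count
matrix and cluster labels (from Cell Ranger + any clustering tool) and want
a reproducible, testable implementation of the downstream steps:

- **Three-rule quality control.** Genes detected in fewer than 0.1% of
  cells are dropped; cells with mitochondrial UMI fraction > 10% are
  dropped; cells whose total UMI falls outside
  `[Q1 − IQR, Q3 + IQR]` of the per-cell totals are dropped. A
  housekeeping-gene detection report is attached as a reliability check
  (advisory, never a filter).
- **Cell-cycle scoring.** Per-cell S and G2/M module scores
  (set mean − expression-bin-matched control mean over log-normalized
  data), with the explicit phase rule: a cell is quiescent (G1) iff both
  scores are negative; otherwise G2M if the G2/M score exceeds the S score,
  S if the converse.
- **Cluster profiles and markers.** Per-cluster mean raw UMI, and a
  one-vs-rest Wilcoxon rank-sum marker ranking (vectorized, tie-corrected
  normal approximation) with Benjamini–Hochberg adjustment and
  `log2((mean_in + 1)/(mean_out + 1))` fold changes.
- **Ligand–receptor communication network.** Against a curated pair table
  (IUPHAR/GtoPdb- or DLRP-style CSV), a molecule counts as expressed in a
  cluster iff its cluster-mean UMI exceeds 1; an edge
  (source, target, ligand, receptor) is emitted whenever the ligand is
  expressed in the source and the receptor in the target, over all ordered
  cluster pairs including self-pairs. Summaries include the chord-plot-ready
  source × target count matrix.
- **Hypergeometric panel enrichment.** For each (cluster, panel) the
  upper-tail probability P(X ≥ k) of drawing k panel genes among n markers
  from a universe of N genes containing K panel genes, with joint BH
  adjustment. A chromosome-21 panel is built directly from the gene
  annotations; disease panels are read from GMT.
- **Pooled correlation network.** Cells are pooled 30 at a time within
  clusters (seeded random partition, remainder dropped), pool profiles are
  mean log-normalized expression, and edges connect pools with Pearson
  r > 0.95. Exported as CSV tables plus GraphML.
- **Synthetic data with planted ground truth.** A negative-binomial
  generator plants cluster markers, a chr21 dosage shift, ligand–receptor
  pairs, lognormal library-size variation and a debris fraction, so every
  stage above is testable end to end with no external data.

All user-facing functions take tabular inputs and return tibbles (or small
result objects with `tidy()`, `glance()` and `autoplot()` methods), so
pipelines compose with the pipe.

## Worked example

```r
library(dosagenet)

# synthetic trisomy-like dataset: 10 clusters x 300 cells, 2000 genes,
# chr21 genes doubled in cluster C4, five planted ligand-receptor pairs
sim <- generate_counts(sim_config(dosage_cluster = "C4", dosage_fold = 2, seed = 1))

qc <- apply_qc(sim$counts)
qc
#> <sn_qc> genes 2000 -> 2000, cells 3000 -> 2783
#>   UMI window [414.0, 1767.0] (Q1 865.0, Q3 1316.0)

labels  <- dplyr::filter(sim$truth$cells, barcode %in% qc$filtered$barcodes)[, c("barcode", "cluster")]
markers <- rank_markers(qc$filtered, labels)
enr     <- enrich_clusters(markers, list(chr21 = build_chr21_panel(qc$filtered$genes)))
head(tidy(enr), 3)
#> # A tibble: 3 x 9
#>   cluster panel     N     K     n     k        p    p_adj overlap
#> 1 C4      chr21  2000    40    61    40 1.34e-68 1.34e-67 "GENE00005;GENE00012;..."
#> 2 C0      chr21  2000    40    21     0 1   e+ 0 1   e+ 0 ""
#> 3 C1      chr21  2000    40    21     0 1   e+ 0 1   e+ 0 ""

comm <- comm_network(qc$filtered, labels, sim$truth$comm_edges[, c("ligand", "receptor")])
tidy(comm)
#> # A tibble: 5 x 4
#>   source target ligand    receptor
#> 1 C0     C1     GENE00241 GENE00242
#> 2 C2     C3     GENE00243 GENE00244
#> 3 C4     C5     GENE00245 GENE00246
#> 4 C6     C7     GENE00247 GENE00248
#> 5 C8     C9     GENE00249 GENE00250
```

Reading the output: QC removed 217 of 3,000 cells (all 60 planted debris
cells plus the tails of the UMI window). The enrichment table shows all 40
chr21 genes among C4's 61 markers (upper-tail hypergeometric
p ≈ 1e−68) and zero chr21 overlap in every other cluster — the planted
dosage effect is recovered exactly where it was planted. The communication
network contains exactly the five planted ligand–receptor edges.

The whole chain (simulate → qc → cellcycle → profile → markers → commnet →
enrich → corrnet) can also be run as one call with a hashed output
manifest:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

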