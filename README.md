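# eecfate

Trajectory and gene-regulatory analysis of enteroendocrine cell (EEC)
differentiation from plate-based single-cell RNA-seq.

EECs are rare hormone-secreting intestinal cells that differentiate from
NEUROG3+ progenitors along a small number of lineages — an enterochromaffin
(EC, serotonin) branch and peptidergic branches (ghrelin/motilin "XMD";
GLP-1/CCK/NTS/GIP/SCT/SST "LINKSD"). Given a raw cell × gene count matrix
with batch labels and a motif→target site-count matrix, `eecfate` runs the
whole analysis such data call for, and ships a synthetic generator with a
planted lineage so that every stage can be verified against ground truth.

## What it computes

| Stage | Core quantity |
|---|---|
| QC + normalization | mito / spike-in / detected-gene filters; equal non-spike-in totals |
| Manifold | binned-dispersion HVGs, PCA, (batch-balanced) kNN graph, Louvain clusters |
| Markers & cycle | Wilcoxon + BH-FDR marker cascade, condition DE, S/G2M phase scores |
| Lineage graph | cluster connectivity confidence (observed/expected inter-cluster edges), diffusion pseudotime from a root |
| Fate trajectories | Markov chain with Boltzmann transitions `P(i→j) ∝ exp(−β(V_j − V_i))` over a potential field V; Monte Carlo walks; exact absorption probabilities `B = (I − Q)⁻¹R`; trajectory-averaged dynamic profiles |
| Motif activity | per-cell TF activities `A·c = (NᵀN + λI)⁻¹NᵀẼ·c` with standard errors; RMS z-scores; lagged expression–activity correlation; lineage-specific regulator selection at thresholds z ≥ 1.4, profile SD ≥ 0.004, peak \|ρ\| ≥ 0.7 |

The absorbing-chain fate probabilities answer "which terminal hormone fate
will this cell's stochastic differentiation path end in"; the activity model
asks whether a TF's target genes deviate from average expression in a
coordinated, lineage-specific, time-resolved way.

## Worked example

```r
library(eecfate)

# default synthetic dataset: 800 cells, 2000 genes, 3 fates, 9 planted
# driver motifs; full pipeline + comparison against the planted truth
bench <- run_recovery_benchmark(seed = 1)
str(bench$metrics)
#> List of 7
#>  $ ari                : num 0.92
#>  $ pseudotime_spearman: Named num [1:3] 0.973 0.974 0.961
#>  $ fate_accuracy      : num 0.989
#>  $ activity_r         : Named num [1:9] 0.986 0.987 0.978 0.985 0.978 ...
#>  $ driver_precision   : num 0.9
#>  $ driver_recall      : num 1
#>  $ n_cells_kept       : int 790
```

Meaning: clustering recovers the progenitor + three terminal populations
(adjusted Rand index 0.92 against the transcriptional ground truth);
diffusion pseudotime correlates with the planted time at Spearman ρ ≥ 0.96
on every branch; 98.9% of branch cells get their true fate as the argmax of
the exact absorption probabilities; estimated TF activities correlate with
the planted activity curves at r ≥ 0.98 per driver; and the differential
selection recovers all nine planted (driver, fate) pairs (recall 1.0) with
one extra cross-lineage call (precision 0.9).

For real data, start from `load_counts()` (MatrixMarket triplet or
delimited table), then `pipeline_config(sce = ..., marker_sets = ...,
motif_targets = ..., tf_map = ...)` and `run_pipeline()`. The methods
vignette (`vignettes/eec-fate-inference.Rmd`) documents the model,
parameters, and design decisions.

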