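---
title: "Lineage trajectories and TF-activity inference for enteroendocrine single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage trajectories and TF-activity inference for enteroendocrine single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eecfate)
```

## The problem

Enteroendocrine cells (EECs) are rare hormone-secreting cells of the
intestinal epithelium. They differentiate from NEUROG3-positive endocrine
progenitors along a small number of lineages — an enterochromaffin (EC,
serotonin-producing) branch and one or more peptidergic branches (ghrelin/
motilin-type "XMD" cells; GLP-1/CCK/NTS/GIP/secretin/somatostatin-type
"LINKSD" cells). Plate-based single-cell RNA-seq of sorted reporter-positive
cells captures snapshots of this process: a few hundred to ~1200 cells, ERCC
spike-ins, several batches or developmental stages, and negative-binomially
overdispersed counts.

`eecfate` implements the full analysis such data call for:

1. quality control and equal-total normalization;
2. highly-variable-gene selection, PCA, (batch-balanced) kNN graphs,
   modularity clustering, 2-D/10-D layouts, cluster expression summaries;
3. marker genes (Wilcoxon rank-sum + BH-FDR + fold-change and
   expressing-fraction filters), condition-wise differential expression, and
   cell-cycle phase scores;
4. a cluster-level lineage graph (connectivity confidence) and diffusion
   pseudotime from a root cell;
5. a potential-energy-biased Markov chain on the cell graph, Monte Carlo
   differentiation trajectories, exact absorption ("fate") probabilities,
   and trajectory-averaged dynamic profiles;
6. per-cell transcription-factor (motif) activities from a ridge linear
   model of motif-target regulation, and selection of lineage-specific
   regulators by three joint criteria;
7. a synthetic-data generator with a planted lineage, planted pseudotime and
   planted regulators, so every stage is testable against ground truth.

## Quality control and normalization

Cells are removed when the mitochondrial count fraction is strictly above a
threshold (0.20 for mouse-like data, 0.50 for human), when the ERCC spike-in
fraction is at or above 0.50, or when fewer than a minimum number of
non-spike-in genes are detected (500 for late-stage mouse plates, 3000 for
E15.5-like plates with deeper coverage, 1000 for human); the boundary
semantics (strict `>`, `>=`, `<`) follow the stated rules exactly, and the
minimum-gene threshold may be set per batch. The mitochondrial fraction is
computed over non-spike-in counts (spike-ins measure capture, not biology);
the spike-in fraction over all counts. Kept cells are scaled so that every
cell's non-spike-in total equals a common target (default: the median
per-cell total, a scale-free choice). A `log1p` layer is an explicit,
recorded optional step: rank-based marker tests are transform-invariant, but
PCA and the activity model are not, so the log layer is used for embedding,
markers and activity inference while dot-plot style summaries use the
normalized (non-log) layer.

## Manifold, clustering, lineage graph

Highly variable genes are ranked by dispersion (variance/mean) standardized
within 20 equal-occupancy mean bins, so variability is judged against genes
of similar abundance; zero-variance genes are never selected. PCA is exact
(`prcomp`) with a fixed sign convention. The kNN graph uses Euclidean
distances with ties broken by cell index; edges carry Gaussian-kernel
weights with per-node adaptive bandwidth (distance to the k-th neighbor),
keeping weights in (0, 1]. Batch-balanced neighbor lists take the
k-per-batch nearest cells within every batch, forcing cross-batch edges;
with one batch this reduces exactly to the plain graph. Community detection
is a pluggable modularity backend (Louvain via igraph), seeded and
deterministic, with sub-clustering by re-running on an induced subgraph and
splicing labels. Where a dataset's populations are sharply separated, a kNN
graph can fall apart into islands; `connect_components()` adds
single-linkage bridge edges (closest pair across components) so that
diffusion and trajectory computations remain defined.

Cluster-level lineage structure uses a connectivity confidence per cluster
pair: observed inter-cluster edge count divided by its expectation under
random edge allocation given cluster degree sums, clipped to [0, 1] (the
unclipped ratio is kept alongside; on random graphs with random labels the
ratio calibrates to 1). Pseudotime is the Euclidean distance from a root
cell in eigenvalue-rescaled diffusion coordinates (components weighted by
lambda/(1 - lambda)); coordinates are normalized by the stationary
distribution so the result is invariant to rescaling all edge weights. The
default root is the most connected cell of the progenitor cluster
(maximal mean edge weight into its own cluster), configurable by explicit
id. Cells disconnected from the root are flagged with infinite pseudotime.

## The trajectory engine

Differentiation is modeled as a discrete Markov chain on the cell graph.
For a non-absorbing cell *i*, the transition probability to *j* in its
closed neighborhood is the Boltzmann weight `exp(-beta (V_j - V_i))`,
normalized per row; all cells of the mature end of each terminal population
are absorbing. `beta` (default 10) sets how strongly walks run downhill.

Three potential fields are provided:

* **Harmonic** (`solve_potential()`): the weighted graph-Laplace solution
  with V = 1 on progenitors and V = 0 on every sink; each interior value is
  the weighted mean of its neighbors (equivalently, the probability of
  hitting a source before a sink). It is exact on boundaries, obeys the
  maximum principle, and admits closed-form checks (a 3-node path gives
  V = (1, 0.5, 0)). On densely connected single-cell graphs, however, the
  harmonic field degenerates into near-constant plateaus on either side of
  the graph's bottlenecks: almost all of the gradient concentrates on a few
  edges, `beta * dV` is ~0 elsewhere, and walks become effectively unbiased
  — they take thousands of steps and mix across branches before absorbing.
* **Pseudotime-derived** (`pseudotime_potential()`, the pipeline default):
  `V = 1 - pt / max(pt)`. This keeps a usable gradient along every lineage
  and is what the pipeline uses to bias the unconditioned chain from which
  absorption probabilities are computed.
* **Distance-to-sink** (`distance_potential()`): per-fate, the normalized
  shortest-path distance to that fate's sink cells. It drives the
  *committed* trajectory ensembles (default 500 walks per fate) from which
  dynamic profiles are computed, so every lineage gets a profile ensemble
  of controlled size even when an unconditioned walk would rarely choose
  it.

Sinks are the mature end of each annotated terminal population: cells at or
beyond the 0.75 quantile of that population's pseudotime. Making the whole
cluster absorbing would terminate walks at the branch mouth and flatten
every dynamic profile; the quantile is configurable (`sink_quantile`).

Fate probabilities come in two forms that cross-validate each other: the
exact absorbing-chain solution `B = (I - Q)^{-1} R` by sparse linear solve,
and the empirical estimator (fraction of visiting walks absorbed per fate,
with binomial standard errors and low-confidence flags below `min_visits`).
Unabsorbed walks (those hitting `max_steps`, default 10x the number of
cells) carry no absorption information and are excluded. Walks are simulated
in compiled code using R's RNG, so ensembles are bit-reproducible from the
seed.

Dynamic profiles rescale each absorbed walk to a normalized position
t in [0, 1] (step index over walk length), average the per-cell quantity in
50 position bins across walks, and smooth with a 5-bin centered moving
average; bin standard errors are reported.

## TF activity inference and differential selection

Per-cell activities solve, for every cell *c*, the ridge system
`A_.c = (N'N + lambda I)^{-1} N' E_.c`, where E is gene-centered log
expression and N the genes x motifs site-count matrix with columns
standardized to zero mean and unit variance over genes. Standardization
puts activities on comparable scales so that one trajectory-variability
threshold is meaningful across motifs. The default
`lambda = 0.1 * mean eigenvalue of N'N`; with `lambda = 0` the solution
equals ordinary least squares (verified against QR and `lm()` oracles).
Standard errors use the per-cell residual variance through the sandwich
form; activities are centered per motif.

A motif's significance is the RMS z-score `sqrt(mean((A/dA)^2))`. Its
lineage dynamics are summarized by the population SD of its activity
profile along each fate's committed trajectories, and by the peak Pearson
correlation between the TF's expression profile and its activity profile
over integer bin lags in a window of +/-25% of the grid (regulation may lead
or lag transcription); the sign at the peak calls activator versus
repressor. A motif is reported for a fate when all three criteria hold:
z >= 1.4, profile SD >= 0.004, and peak |rho| >= 0.7. The specificity label
is the exact set of passing fates, and within each fate motifs are ordered
by activation onset (first bin above half the profile range).

## The synthetic generator

`generate_dataset()` plants: uniform pseudotime; a progenitor pool
branching at t = 0.3 into three terminal fates (equal proportions); three
driver motifs per fate with steep sigmoidal activity rises at staggered
onsets (0.4, 0.55, 0.7) and low-amplitude white-noise null motifs; a sparse
site-count matrix (targets per motif ~ Poisson(40), counts >= 1) over
background genes; one dedicated TF gene per motif whose expression tracks
its activity; 40-gene marker programs per population (terminal markers ramp
on with midpoint 0.075 past the branch point, progenitor markers ramp off);
a 30-gene proliferation program in 10% of progenitors; per-gene batch
shifts over two batches; log-normal library sizes; negative-binomial counts
(size 2); 20 ERCC spike-ins at fixed means independent of cell state; 2%
mitochondrial genes; and 10 damaged cells whose expected mitochondrial
fraction is 0.75 — far enough above the 0.5 QC threshold that count noise
cannot pull a damaged cell back under it. Planted effects are about 2
natural-log units, the scale of a clear lineage program, chosen so that the
planted structure is genuinely recoverable rather than borderline. All
draws flow from one seeded generator and the caller's RNG state is
restored.

Because lineage commitment is latent, the generator distinguishes the
planted branch (`truth$branch`, assigned at t >= 0.3) from the
*transcriptional* discretization (`truth$expressed_branch`: a committed
cell reads as its branch only once its marker program is at least half
induced). Cluster-recovery metrics use the transcriptional labels — a cell
committed 0.02 time units ago is, by construction, indistinguishable from a
progenitor — while pseudotime, fate and driver metrics use the latent
truth.

What the generator does *not* emulate: UMI saturation and amplification
chemistry, doublets, ambient RNA, and the hormone co-expression gradients
of real EEC subtypes. Passing the recovery suite therefore shows that the
pipeline's machinery is correct and well-calibrated on overdispersed
branching data, not that it is robust to every artifact of real plates.

## Default problem sizes and runtime

The recovery benchmark (`run_recovery_benchmark()`) runs the default
800-cell / 2000-gene dataset end to end in about half a minute on one core:
clustering at a small resolution grid (0.1-1) choosing the partition
closest to the four planted populations, 2000 unconditioned walks, 500
committed walks per fate, and the full activity/selection stack. Unit
tests use 200-250 cells. Monte Carlo oracles use 1e5 walks per toy chain.

## A worked run

```{r, eval = FALSE}
library(eecfate)

bench <- run_recovery_benchmark(seed = 1)
str(bench$metrics)
#> List of 7
#>  $ ari                : num 0.92
#>  $ pseudotime_spearman: Named num [1:3] 0.973 0.974 0.961
#>   ..- attr(*, "names")= chr [1:3] "EC" "XMD" "LINKSD"
#>  $ fate_accuracy      : num 0.989
#>  $ activity_r         : Named num [1:9] 0.986 0.987 0.978 0.985 0.978 ...
#>  $ driver_precision   : num 0.9
#>  $ driver_recall      : num 1
#>  $ n_cells_kept       : int 790

report <- pipeline_report(bench$res)
report$motif_categories
#>   specificity n_motifs
#> 1          EC        3
#> 2      EC+XMD      1
#> 3      LINKSD      3
#> 4         XMD      2
```

All nine planted drivers are recovered in their own fate (recall 1.0); one
XMD driver additionally crosses the correlation threshold in EC, which is
why it appears as `EC+XMD` and precision is 0.9.

## Known limitations

* The harmonic potential is retained as a fully tested primitive but is not
  the pipeline default for the reason documented above; on graphs with
  pronounced bottlenecks its plateaus make `beta` effectively inert.
* Committed ensembles bias walks toward their fate by construction; they
  are the estimator for *conditional* dynamic profiles and must not be used
  to estimate fate probabilities (the unconditioned chain is).
* A nonlinear 10-D layout (`fate_backend = "umap"`) can fragment sharply
  separated populations into islands; single-linkage bridges keep the graph
  connected but can route geodesics through the wrong branch. The linear
  PCA fate graph is the default for this reason.
* Marker fold changes use a pseudocounted ratio of group means capped at
  +/-10; "expressed" means a nonzero normalized count. Both are
  conventions, configurable, and stated in the function documentation.
* Exact Wilcoxon p-values are used only for tie-free groups of at most 10
  cells; otherwise the normal approximation with tie correction applies.
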