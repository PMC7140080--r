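---
title: "Quantifying drug response in 3D scaffold tumour models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug response in 3D scaffold tumour models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldomics)
```

## Overview

`scaffoldomics` packages three analyses that are commonly combined when an
epigenetic drug is screened against a 3D tumour culture model (for
example, an HDAC/LSD1 inhibitor against an aggressive paediatric CNS
tumour line grown in a fibrin scaffold):

1. an **imaging arm** that quantifies how treatment changes 3D cell
   clustering from two-channel confocal z-stacks;
2. an **expression arm** implementing the standard single-cell
   count-matrix statistics around a Wilcoxon marker test; and
3. a **network arm** that seeds multi-level interaction networks with
   differentially expressed genes (DEGs) and asks which biological
   processes are *consistently* over-represented across levels.

Every stage is exercised end to end on synthetic data with known ground
truth, generated by the package itself. This vignette explains the models
and conventions behind each stage, the tunable parameters that matter,
and what the synthetic benchmarks do and do not demonstrate.

## Imaging arm

### Separating glass from scaffold

Confocal stacks of scaffold cultures contain two populations of signal: a
dense, coverslip-adherent 2D cell layer ("glass") at one end of the z
range, and cells growing freely in the 3D matrix. The cropping rule works
on per-slice summed intensities, one sum per channel per slice
(`sum_slice_intensities()`):

* Tukey inner fences, `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, are computed once
  per channel from all slice sums. Quartiles use linear interpolation
  between order statistics (the `quantile()` type 7 convention); this
  convention is declared because the fences are otherwise ambiguous for
  small slice counts.
* The reference slice is the **highest** z index containing a voxel equal
  to a channel's global maximum, taken across channels. Constant channels
  make every slice a maximum, so a degenerate channel pushes the
  reference to the last slice — a deliberate consequence of the tie rule,
  and harmless because removal also requires an outlying sum.
* A slice is removed iff it lies **above** the reference *and* its sum is
  outlying in **either** channel. The union-over-channels rule and the
  inclusion of below-lower-fence slices are the conservative readings of
  "outlying"; both are single-pass decisions (fences are not recomputed
  after removals).

The lowest removed index is recorded as the dividing line between glass
and scaffold signal. Cropping is idempotent on its own output whenever
the second pass finds no new outliers.

### Segmentation

The cell-dye channel is thresholded with Otsu's method over a 256-bin
histogram (integer levels for 8-bit data; equal-width bins over the
observed range otherwise). Foreground is *strictly greater* than the
threshold and variance ties break toward the lowest threshold, so the
result is reproducible against an exhaustive search. Connected components
use 26-connectivity (face + edge + vertex), the convention of 3D object
counters in this field; 6-connectivity is available. Objects smaller than
10 voxels are discarded ("from ten pixels to maximum volume" read as
voxels, since the objects are 3D), and objects touching any of the six
faces of the cropped volume are excluded by default — the stricter
reading, configurable via `exclude_edges`.

### Clustering quantification

Object volumes (µm³) are summarised as density histograms (bar areas sum
to 1), optionally restricted to the "peak region" domain
`[0, mean + 2 sd]` with the moments taken from the full sample. The
default bin width is Freedman–Diaconis, chosen because no width is
canonical for these volumes.

The scalar metrics operationalize "clustered vs non-clustered" with a
declared cutoff: an object whose volume is at least twice a calibrated
single-cell volume counts as a cluster. The cutoff is an artifact-defined
reading of what is otherwise a qualitative histogram comparison; the
calibrated `unit_volume` defaults to the mode of the volume histogram
(the most common object size approximates a single cell) and is always
reported alongside the fractions. `compare_conditions()` tabulates the
metrics without inferential statistics — none are implied by the
histogram-shape comparison this mirrors.

## Expression arm

The count-matrix statistics follow the conventions of droplet single-cell
workflows:

* **QC trim.** Cells with *more than* 40,000 molecules are removed
  (strict inequality; a cell at exactly the threshold is kept). The
  threshold guards against doublets and broken droplets.
* **Percent mitochondrial RNA** is `100 * mito counts / total counts` per
  cell, computed from the count matrix. This approximates read-level
  percentages, which would need the raw alignments.
* **Normalization.** Each cell is divided by its size factor,
  `total / median(total)`; every normalized cell total then equals the
  median raw total exactly, which the tests assert to 1e-9.
* **Differential expression.** The natural-log fold change
  `ln((mean_a + 1)/(mean_b + 1))` is computed on normalized values with a
  pseudocount of 1; genes pass to testing only when `|LFC| > 0.25` (a
  natural-log convention), so the Bonferroni factor counts only tested
  genes. P values come from a two-sided rank-sum test: exact enumeration
  of rank assignments when both groups have at most 10 cells (the
  enumeration handles ties exactly under the permutation null; the
  two-sided p is `P(|W - E W| >= |w - E W|)`), otherwise a tie-corrected
  normal approximation. Whether the significance filter uses raw or
  adjusted p is genuinely ambiguous in workflows of this kind; both are
  reported and the filter defaults to the adjusted value, the stricter
  choice.

`dotplot_stats()` (mean expression and percent expressing per cluster)
and `population_fraction()` (fraction of cells below a metric threshold
per group, e.g. percent mtRNA under 10) provide the standard population
summaries. Clustering itself is an input — graph-based clustering and
embedding are deliberately out of scope.

## Network arm

DEGs (adjusted p < 0.05, strict) seed one first-order network per
systems-biology level: the seeds plus their direct interactors, with all
edges among included nodes. Interaction knowledge arrives as edge tables
supplied by the user — live database retrieval is out of scope, so
provenance lives in the level tag. All graphs are undirected and simple;
regulator directionality is collapsed so that networks merge cleanly.

* **Trimming** removes non-seed nodes below per-level degree (and
  optionally betweenness) thresholds, both computed once on the untrimmed
  network; seeds are always protected, matching tools that preserve query
  genes. Betweenness is exact, unnormalized shortest-path betweenness.
  When both thresholds are set they apply conjunctively (a node must meet
  both), with `rule = "either"` available since the convention is not
  universal. The 200–600-node budget is a warning, not an error: the
  budget describes production-scale networks, and synthetic fixtures are
  legitimately smaller.
* **Merging** takes the union over node ids and reports replicates: node
  ids appearing in more than one input and unordered, level-agnostic
  edges appearing in more than one input.
* **Dense regions** follow the published MCODE scheme: vertex weight =
  (highest k-core of the closed neighbourhood) × (density of that core);
  greedy expansion from the top-weighted unvisited seed admitting
  neighbours within 20% of the seed weight; haircut to the 2-core; and
  the defaults degree cutoff 2, node score cutoff 0.2, k-core 2, max
  depth 100. Regions are disjoint by construction and ranked by
  density × size.

Over-representation uses the upper-tail hypergeometric probability
`P(X >= k)` with BH-FDR across terms within one run. The universe is the
set of genes carried by the annotation collection; because ORA p values
depend on this choice, the universe is an explicit argument everywhere.
A term is significant in a level at FDR q < 0.1, and the consensus keeps
terms significant in at least `min_networks` levels. The default is 3
*inclusive*: descriptions of this rule oscillate between "in three
networks" and "more than three networks", so the parameter reaches both
readings. Terms without a family label from the (optional, manually
curated, never inferred) mapping are surfaced as isolated-term candidates
for manual dismissal rather than dropped automatically.

## Synthetic data: what it emulates and what it does not

`simulate_stack()` renders cells as filled digital spheres (a voxel
belongs to a cell iff its centre is within the radius), the simplest
shape with an exact analytic voxel-count oracle, over a constant
background with additive Gaussian noise clipped to the 8-bit range —
chosen to keep Otsu behaviour predictable. Cell clusters grow as chains:
each member is displaced from the previous one in an isotropic random
direction with the displacement magnitude clamped into `[r, 2r - 1]` and
re-drawn when it would fold back onto a non-adjacent member. Pure
isotropic Gaussian displacement was rejected because it routinely either
disconnects intended clusters or collapses them onto one sphere,
destroying the very ground truth the fixture exists to provide; the
clamped chain guarantees each planted cluster renders as one connected
object whose volume grows with its cell count. The glass layer is drawn
slightly dimmer per voxel than scaffold cells (`gain_scale`, default
0.85) while being far denser: its slice sums dominate, but the per-voxel
absolute maximum stays in the scaffold, which is exactly the regime the
cropping rule assumes. Glass centres are sampled from a radius-extended
z range and clipped to the layer so coverage is uniform across every
glass slice.

No point-spread function, attenuation with depth, autofluorescence or
anisotropic blur is modelled; passing the imaging benchmarks shows the
*rules* are implemented faithfully, not that they are robust to real
optics. Default stack geometry is 28 slices of 96×96 at 2×1×1 µm per
voxel — small enough that the whole imaging suite runs in seconds while
still leaving room for well-separated objects.

`simulate_counts()` draws negative-binomial counts with a per-condition
mitochondrial block whose mean is scaled to hit a target expected mito
fraction, a stem-like subpopulation with marker means elevated by a fixed
fold, and an exact high-total tail (tail cells are integer-scaled until
they strictly exceed the trim threshold, so the trimmed fraction is exact
by construction). Library-size variation, gene–gene correlation, batch
effects and doublets are not modelled. `simulate_networks()` plants one
clique among the DEGs at a designated level and one gene set biased
toward the DEG list among uniform background terms; degree distributions
are not scale-free and edge counts are small, so the benchmarks probe
correctness of the graph operations, not performance at interactome
scale.

All generators consume a single RNG seed through one global stream per
call and restore the RNG state afterwards; identical spec + seed is
byte-identical output, which the determinism tests assert on written
files.

## Numerical choices and degenerate inputs

* Otsu on a constant image is an error ("degenerate histogram"), as is a
  histogram request with no volumes, an empty study set or universe in
  ORA, a zero-total cell in normalization, and a trim that removes every
  cell.
* Fences need at least 4 slices; cropping refuses to remove all slices.
* `which.max` tie-breaking gives the lowest Otsu threshold and the
  first-ranked MCODE region deterministically.
* Bonferroni is `min(1, p * m)` with `m` the number of *tested* genes.
* The `fluff` MCODE option is accepted but off, matching the original
  defaults; haircut equals taking the 2-core, the fixed point of
  iteratively removing singly connected vertices.

## Orchestration

`run_config()` carries every threshold with its default
(`min_voxels = 10`, `connectivity = 26`, `max_molecules = 40000`,
`lfc = 0.25`, `alpha = 0.01`, `alpha_deg = 0.05`, `q_threshold = 0.1`,
`min_networks = 3`, per-level trim thresholds ppi 10 / tf 25 / mirna 25 /
coexpression 2 + betweenness 4, MCODE defaults) and round-trips through
YAML. The three arms (`run_imaging_arm()`, `run_expression_arm()`,
`run_network_arm()`) write TSV artifacts plus a manifest with parameter
echoes and MD5 checksums; manifests deliberately contain no wall-clock
fields so reruns on identical inputs are byte-identical. A thin
command-line wrapper over these functions ships in
`inst/scripts/scaffoldomics.R`.

## A worked miniature

```{r imaging-demo}
sim <- simulate_stack(stack_spec(
  shape_zyx = c(28, 96, 96), n_singletons = 10, n_clusters = 5,
  cells_per_cluster = c(4, 4),
  glass_layer = list(z_range = c(24, 28), density = 0.3),
  seed = 1))
cr <- crop_stack(sim$stack)
cr$profile$removed          # the planted glass slices
seg <- segment_stack(cr$stack)
nrow(seg$table)             # 10 singletons + 5 clusters
clustering_metrics(seg$table,
                   unit_volume = 33 * voxel_volume(sim$stack))
```

## Known limitations

* The singleton/cluster cutoff (2 × unit volume) cannot distinguish one
  large cell from a two-cell cluster; it is a declared operationalization
  and is reported as such.
* Measurement is purely geometric on the thresholded mask; intensity
  redirection, watershed splitting of touching cells and
  intensity-weighted centroids are out of scope.
* Percent mtRNA from counts understates read-level percentages when
  mitochondrial reads map at different rates.
* The exact rank-sum path enumerates `choose(n, n_a)` assignments and is
  only engaged when both groups have ≤ 10 cells.
* GO hierarchy structure is not traversed; gene sets are flat.
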