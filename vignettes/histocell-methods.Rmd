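---
title: "Methods: hierarchical cell and tissue phenotyping of H&E whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical cell and tissue phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(histocell)
```

## The model

`histocell` treats a whole-slide image (WSI) as a hierarchy: nuclei
are localised, each nucleus becomes a classified cell, and cells
become nodes of a spatial graph over which tissue microstructures are
inferred. The guiding assumption is biological: a tissue
microstructure *is* its cellular community, so a classifier that
aggregates the cells in a neighbourhood can recover tissue identity at
single-cell resolution, without pixel-level tissue masks.

### Coordinate frame and tiling

All coordinates are 0-based pixel indices in a frame rescaled to
0.1109 µm/px (x rightwards, y downwards, origin top-left). Scanners
differ in native resolution, so rasters are resampled (bilinear) by
`native_mpp / target_mpp`; coordinates never change meaning. Slides
are tiled into 1600 × 1200 px patches with a 200 px overlap — wide
enough that any nucleus truncated at one patch border appears whole in
the neighbouring patch. The final row/column origin is clamped to
`dim − patch` rather than padded, so every raster is full size and the
detector never sees a synthetic border. Patches whose mean channel
value exceeds 245 (bare glass) or falls below 10 (scanner border) are
excluded as background; the filter runs after rescaling, on the full
patch.

### Nucleus localisation

Detectors are pluggable behind a single contract — per-patch
axis-aligned boxes with scores in [0, 1] — because the detection model
itself is interchangeable while everything around it (tiling, pooling,
deduplication, evaluation) is fixed. The package ships an oracle
detector that reads ground truth with configurable jitter and drop
(for pipeline tests), and a trainable classical blob detector:
dark-pixel thresholding, connected components, area gating and
darkness-weighted centroids. "Training" the blob detector is
calibration: each epoch evaluates one candidate (threshold, minimum
area) pair from a seeded search sequence on validation patches and
records its F1; the best-validation epoch is kept, mirroring
best-checkpoint selection. Components touching a patch border are
discarded — the overlap guarantees the same nucleus appears whole
elsewhere, and truncated blobs would yield displaced centroids that
survive deduplication as spurious near-duplicates.

Pooled predictions are deduplicated greedily in descending confidence
(ties: lower y, then lower x); a prediction is kept iff no kept
prediction lies strictly within 4 px. Keeping the higher-confidence
member is a choice — the rule's source states only that duplicates are
removed — as is the strict inequality, mirroring the strict `< 3.3 µm`
evaluation threshold.

Evaluation uses a one-to-one matching between predictions and truth
over pairs closer than 3.3 µm: maximum cardinality first, minimum
total distance among maximum matchings second (implemented as
maximum-weight bipartite matching with weights `C − d`). An optimal
matching was chosen over greedy because it is order-free and
reproducible; tests verify it against exhaustive search on instances
with ≤ 7 points per side.

### Cell classification

Each nucleus yields a crop spanning `[x − s/2, x + s/2) × [y − s/2,
y + s/2)` (default s = 200 px); out-of-slide area is padded with 255,
matching the pale background. The shipped trainable classifier is a
single-hidden-layer softmax network (`nnet`) over a PCA projection of
downsampled RGB crop features. The hidden layer has 64 units whose
activations are the per-cell embedding passed to the graph stage; the
PCA front-end (default 24 components) keeps the optimiser's weight
count small, which matters because `nnet`'s BFGS needs memory
quadratic in the weight count. Training uses inverse-frequency case
weights (the oversampling scheme: expected class frequencies under
weighted resampling are uniform), optional per-epoch stain
augmentation, and best-validation-accuracy selection across epochs.

Stain augmentation works in optical-density space: the image is
deconvolved against a fixed two-row H&E stain matrix (normalised
haematoxylin ≈ (0.65, 0.70, 0.29) and eosin ≈ (0.07, 0.99, 0.11)
vectors), each stain concentration channel is scaled by
U[1 − α, 1 + α] and shifted by U[−β, β], and the image is recomposed
and clipped. The residual component of OD outside the two-stain plane
is preserved, so α = β = 0 is an identity up to floating-point
round-trip. Both α and β default to 0.15 — a moderate jitter chosen
once as representative of realistic between-batch stain variation; the
exact augmentation families used elsewhere are not fixed by any
published parameter set.

Syncytial-knot post-processing runs as a single pass over the original
prediction set: for each knot, other knots within ≤ 50 px are counted;
knots with fewer than 4 such neighbours are relabelled
syncytiotrophoblast (their knot probability mass moves to the
syncytiotrophoblast column so the label remains the argmax), and the
remaining knots are collapsed — processed in descending neighbour
count with positional tie-breaks, each surviving centre removes its
in-radius knot neighbours. The inclusive boundary, the exclusion of
the centre from its own count, the precedence of relabelling over
removal, and the deterministic processing order are all package
choices where the underlying rule is silent; the test suite re-checks
them against an independent restatement on random configurations.

### The cell graph

Nodes carry nucleus coordinates and cell embeddings. The edge set is
`sym(kNN₅) ∩ Delaunay ∪ self-loops`: kNN is symmetrised by union
(j among i's 5 nearest *or* vice versa) before intersecting with the
Delaunay triangulation. Union-then-intersect maximises recall of true
adjacencies while the Delaunay term caps long edges that would cross
tissue boundaries. Ties in kNN break by node index. For degenerate
inputs (n < 3 or collinear points) no triangulation exists, so the
Delaunay term is defined as the complete graph and the edge set
reduces to the kNN edges. The triangulation is an incremental
Bowyer–Watson implementation; tests verify exact edge-set equality
against an independent empty-circumcircle oracle on random point sets.

Dataset splits are region-based: every node takes the split of its
containing region polygon, and the splitter reports boundary-crossing
edges and the minimum hop distance from held-out nodes to training
nodes. Random node-level splits would leak: with an L-layer network a
validation node within L hops of training nodes shares most of its
receptive field with them. Held-out regions must therefore be large
relative to the receptive field — the synthetic graph generator places
region seeds on a jittered grid so regions have comparable areas, and
assigns several disjoint regions per class so a class is never absent
from training.

### Tissue GNN

The node classifier is a GraphSAGE-mean network written directly on
sparse matrix operations: layer l computes
`H_l = ReLU(H_{l−1} W_self + A H_{l−1} W_neigh + b)` where A is the
row-normalised adjacency including self-loops, followed by a linear
softmax head; gradients are derived analytically and optimised with
Adam. The loss is weighted cross entropy with inverse-frequency class
weights normalised to mean 1 — with balanced classes it reduces
exactly to the unweighted loss (asserted in tests). During training
the adjacency is re-sampled each epoch (uniform, without replacement,
capped per node) and the loss is taken on a random batch of training
nodes; inference always uses full neighbourhoods and is deterministic
and permutation-equivariant. Model selection follows a two-graph
protocol: validation accuracy is computed without sampling on a k = 8
intersection graph over the same nodes, while training and final
inference use the k = 5 graph.

Two configuration profiles exist. The full-scale profile (16 layers,
256 hidden units, 2000 epochs, lr 0.001, batch 200, neighbour sample
400) is the reference configuration; the `desk` profile (4 layers, 64
hidden units, 200 epochs, lr 0.01) is the default and is what the test
suite exercises — at fixture scale (≈ 2000 nodes) it recovers
regionally organised labels from features with class separation 4 at
≥ 95 % held-out-region accuracy, and stays at chance when features are
uninformative.

## Quantification and comparison

Per-slide summaries count cells per class (after knot post-processing,
so collapsed cluster members are not double-counted) and tissue votes
per node. Tissue "proportions" are node-level — each cell contributes
one vote — because predictions are per node; a structure-level
definition would need segmentation the pipeline does not produce.
Occupied area is estimated as the number of non-overlapping grid
patches (default the 1600 × 1200 tiling patch, configurable)
containing at least one nucleus, times the patch area in mm²;
densities divide counts by that area. Groups are compared per variable
by two-sided Welch's t-tests with Bonferroni correction applied within
the family of variables tested in one comparison (cells and tissues as
separate families). Literature-range flags use inclusive bounds.

## Agreement analysis

Cohen's kappa uses the standard marginal-frequency chance correction;
the multi-rater headline number is the mean of pairwise kappas, which
is reported as such (other aggregations exist and none is canonical
for this design). Per-class kappa binarises each rater's labels
class-vs-rest and averages pairwise. Majority voting excludes
"unclear"/"not listed" votes and requires a strict plurality; ties
yield no majority rather than an arbitrary winner. The model-vs-rater
comparison regresses per-class PR-AUC on per-class kappa (OLS, R² as
squared Pearson correlation).

## Synthetic fixtures: what they do and do not show

The slide generator places nuclei by Poisson-disk rejection sampling
(expected count = density × area, minimum separation default 7 µm),
assigns each nucleus the class mixture of its Voronoi tissue region,
and renders anisotropic Gaussian blobs whose colour, size and
eccentricity depend on class, on a pale (value 248) background.
Defaults — 4 cell classes, 3 tissue regions, 4000 nuclei/mm²,
0.1109 µm/px — were chosen once as a plausible desk-scale emulation of
placental parenchyma; the full 11/9 taxonomy is available. The
generator reproduces the *statistical structure* the pipeline assumes
(localised class-dependent nuclei, spatial tissue organisation,
background separability) but not real histology: no stain texture, no
touching/overlapping nuclei, no out-of-focus regions, no artefacts.
Passing fixtures therefore demonstrates that the algorithms implement
their definitions and that the pipeline composes correctly — not that
the desk-scale models would reach published performance on clinical
slides, which requires trained deep models and real data.

## Numerical choices and degenerate inputs

* Bowyer–Watson uses a relative tolerance in the in-circumcircle test;
  cocircular degeneracies are resolved by that tolerance, and fixtures
  use random (general-position) coordinates.
* `evaluate_detection` defines F1 = 1 when both sides are empty, 0
  when exactly one is.
* Welch's test returns p = 1 when both groups have zero variance and
  equal means.
* Kappa returns 1 when both raters are constant and identical
  (expected agreement 1).
* `split_dataset` uses largest-remainder rounding so split sizes are
  deterministic in n.
* The PNG/TIFF readers refuse to open a slide whose µm/px cannot be
  determined; a silent default would corrupt every physical
  measurement downstream.

## Persistence and resume

The results store writes each batch as an RDS chunk and only then
appends a ledger line marking the patch origin complete; a crash
between the two leaves an unreferenced chunk that reads ignore.
Resume returns exactly the unledgered origins, and a configuration
hash prevents resuming under changed parameters. Tests assert that
interrupt-and-resume produces predictions identical to an
uninterrupted run.

## Problem sizes

The test suite and acceptance script run entirely on synthetic
fixtures sized for a single CPU: slides up to 1600 × 1200 px with a
few hundred nuclei, cell graphs of 1200–2000 nodes, 60–150 GNN epochs,
500 matching-oracle trials and 200 graph-oracle point sets. These
sizes were chosen so each property is exercised well away from trivial
regimes while the whole suite completes in minutes.

## Known limitations

* The shipped detector and classifier are classical/shallow models
  behind the same contracts as large neural models; they are intended
  for fixtures and as reference implementations of the surrounding
  logic, not as replacements for trained deep networks on real slides.
* The GNN trains full-graph per epoch with sampled adjacencies, which
  is appropriate at fixture scale; slide-scale graphs (10⁵–10⁶ nodes)
  would need mini-batched neighbourhood expansion.
* Stain augmentation uses one fixed H&E basis; per-slide adaptive
  deconvolution is out of scope.
* The agreement module implements pairwise-kappa aggregation only
  (no Fleiss/Krippendorff variants).
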