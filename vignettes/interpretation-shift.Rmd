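---
title: "Simulating and measuring the interpretation shift of PHH3-assisted mitosis annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring the interpretation shift of PHH3-assisted mitosis annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stainshift)
```

## The scientific problem

The mitotic count in H&E-stained tumor tissue is a standard prognostic
marker, but identifying mitotic figures (MFs) from morphology alone has
notoriously low inter-rater agreement. Immunohistochemistry against
phospho-histone H3 (PHH3) marks mitotic nuclei specifically, so a
co-registered, re-stained PHH3 slide overlaid on the H&E image is an
attractive aid when building MF annotation datasets: raters overlook fewer
figures and agree with each other far more.

The catch is an *information mismatch*. PHH3 is most sensitive to early
mitosis: many early-prophase cells carry a clear marker signal while showing
no recognizable mitotic morphology in H&E (conversely, some late telophases
are H&E-obvious but weakly labeled). A rater who has seen the marker may
also call the H&E morphology more permissively — a hindsight bias. Labels
produced with PHH3 assistance therefore contain objects that are invisible
from the H&E pixels alone. From the perspective of an H&E-only detector such
labels act as asymmetric label noise: they depress measured recall when used
for evaluation, and they drag the decision boundary toward
non-figures when used for training. A dual-stain detector that *sees* both
images has no mismatch and can exploit the cleaner labels.

`stainshift` implements this entire study design as a reusable, fully
synthetic pipeline: a generator for co-registered H&E/PHH3 image pairs with
known cell-level ground truth, a simulator for a two-phase multi-expert
annotation study, the consensus and agreement statistics, compact single-
and dual-stain detectors with the train-label x eval-label experiment grid,
and the latent-space decision-boundary analysis. Everything runs at desk
scale on one CPU.

## The synthetic study and what it emulates

`study_config()` fixes the study conditions. The defaults encode the
emulated experiment: 13 raters, 20 regions of interest, 0.25 um/px, and per
image about 32 true MFs, 80 non-mitotic nuclei and 12 MF lookalikes. The
mitotic-phase mixture is 24/24/37/6/9 percent for
prophase/prometaphase/metaphase/anaphase/telophase — the 48/37/15
pro-prometa/meta/ana-telo split reported for PHH3-discovered figures,
adopted here as the global mixture because no phase distribution for the
full MF population is available. A fraction `mismatch_fraction = 0.56` of
PHH3-positive pro/prometaphase cells is flagged *not H&E-visible* (the
mismatch mechanism; 0.56 is the re-assessed fraction of newly found figures
judged unrecognizable, 172 of 308). Telophases carry the marker with
probability 0.7 — the marker's reduced late-phase sensitivity is reported
only qualitatively, so this is a package choice. Cell centers keep a minimum
separation of 7.5 um (one nucleus diameter) so that consensus clustering
can never merge two distinct cells.

Every H&E-visible figure (and every lookalike) carries a latent
*morphological distinctness* in \[0, 1\]. Distinctness is the central
random variable of the generator: it drives both how clearly the figure is
rendered and how likely raters are to accept it, so that the cells missing
from a morphology-only consensus are the genuinely faint ones — the
property that makes consensus membership meaningful to a detector. Rendering
is deliberately stylized: eosin-like background, disc nuclei, and
condensed-chromatin glyphs (phase-specific shapes) only where `he_visible`
is set, with the glyph contrast tracking distinctness down to a small floor
(borderline figures are rendered borderline). The binding contract — tested pixel-for-pixel — is that
a mismatch cell is drawn by exactly the same code path as a non-mitotic
nucleus: no detector can distinguish them from the H&E raster. The PHH3
raster shows brown immunolabel discs at deformation-displaced positions;
the residual registration error is a smooth sinusoidal displacement field
bounded by `max_deformation_um` (default 1 um). Because the mechanism under
study is informational rather than textural, photorealism is a non-goal;
consequences for interpretation are discussed under *Limitations*.

`rater_profiles()` draws a panel of annotator behaviours built around
internal cutoffs on the distinctness scale. A rater with marginal
sensitivity `s` accepts a figure of distinctness `d` with probability
`clamp((d - (1 - s) + tau/2)/tau, 0, 1)`: over the uniform distinctness
distribution the marginal detection rate is exactly `s` (phase-wise
defaults centred on 0.25-0.58, lowest for prophase), while the softness
`tau` (default 0.5) sets how much raters disagree about individual
borderline figures. Three error channels complete the profile: shared
lookalike confusions (rate 0.25 — convincing mimics fool many raters and
occasionally reach consensus), idiosyncratic misreads of ordinary nuclei
(rate 0.12 per nucleus — personal errors that essentially never reach
consensus but pull each rater's precision down), and about 1 um of
localization jitter. With the PHH3 overlay the screening sensitivity is
0.95 regardless of distinctness, false positives drop to 30% of their
H&E-only rates (neither lookalikes nor ordinary nuclei carry the marker),
and a mismatch cell is upgraded to "identifiable in both stains" with
hindsight-bias probability 0.65. These centres were calibrated once against
the emulated study's published statistics — phase-1 precision near 0.52 and
F1 near 0.61 rising to about 0.85 with assistance, count ICC 0.87 rising to
0.93, and a phase-2 consensus about 1.8 times the phase-1 one. The
package's claims remain directional, never about reproducing the original
study's exact values, which would require the original raters and images.
The washout between the two study phases is modeled as independent random
substreams per (image, phase, rater) — a rater retains no memory.

```{r}
cfg <- study_config(rng_seed = 1)
study <- generate_study(cfg)
label_sets <- derive_label_sets(study)
glance(rater_agreement(study))
```

## Consensus clustering and agreement statistics

Annotations of one image are clustered greedily: processed in a
deterministic order (rater id, then x, then y), each annotation joins the
*nearest* existing cluster whose running-mean centroid lies within 7.5 um
and that does not yet contain a mark from the same rater, otherwise it
founds a cluster; ties break toward the lowest cluster index. The published
rule fixes only the radius; the processing order, the running-mean centroid
update and the one-mark-per-rater constraint are package decisions, chosen
for determinism and because supports must count experts. A deliberately
naive re-implementation of the same ordered rule serves as a brute-force
oracle in the tests; an exact membership match is required on hundreds of
random instances. Consensus sets keep centroids supported by at least
`min_support` raters (6 for the 13-rater panel — half of the 12 remaining
experts in the leave-one-out view, the same threshold the full-panel counts
use). Raising the threshold can only shrink the consensus, which is tested
as a monotonicity property.

Per-rater agreement compares each rater with the consensus of the other
twelve (greedy nearest-first one-to-one matching within 7.5 um — the
matching radius is not specified in the emulated protocol, so the
clustering radius is reused; a maximum-cardinality matching oracle bounds
the greedy matcher in the tests). The count ICC is the two-way
mixed-effects consistency form for a fixed panel, reported as the
average-of-k reliability ICC(3,k) = (MS_T - MS_E)/MS_T, whose identity with
the Spearman-Brown adjustment of ICC(3,1) is verified to 1e-10. Fleiss'
kappa summarizes the post-hoc three-expert morphology verdicts. Phase
differences use a paired t-test with Shapiro-Wilk normality checks and
Bonferroni-corrected significance; identical vectors yield an explicitly
undefined statistic rather than a number.

## The detectors

The detector is an anchor-free, fully convolutional one-stage design:
a three-level feature pyramid built from backbone blocks 2-4, with a shared
head that predicts per-location class score, centerness
(`sqrt(min(l,r)/max(l,r) * min(t,b)/max(t,b))`, exactly 1 at a box center)
and four side distances, decoded as `exp(raw) * stride`. Point labels
become 50 px square boxes (a nucleus-scale box at 0.25 um/px; the emulated
protocol never states its point-to-box rule). Locations are assigned to
pyramid levels by regression range (`c(0, 24, 48, Inf)` px by default) and
to the smallest containing box. The loss is the standard focal
classification loss (alpha 0.25, gamma 2), smooth-L1 on stride-normalized
side distances, and binary cross-entropy on centerness, averaged over
positive locations. Because no deep-learning framework is available in this
R environment, the convolutional core (im2col/GEMM convolutions, fused
channelwise LayerNorm+ReLU, nearest upsampling, AdamW) is implemented in
the package itself with hand-derived backpropagation, validated by
finite-difference gradient checks in the test suite.

The dual-stain variant adds a second, PHH3-specific backbone. At each
pyramid level the two feature maps are concatenated along channels,
layer-normalized, reduced back to the single-branch width by a 1x1
convolution and rectified — one independent merging network per level. The
1x1 fusion weights start as an identity pass-through of the H&E half plus
small random mixing of the PHH3 half: a residual-style initialization that
makes the fused network well-conditioned from the first step (with a
conventional random initialization the PHH3 pathway is frequently never
discovered within a desk-scale schedule). LayerNorm here normalizes across
channels independently at each spatial position; normalizing whole feature
maps is the documented alternative. Channelwise LayerNorm also replaces
batch statistics inside all backbones, since training runs at batch sizes
of one or two where batch normalization is meaningless.

Three backbones are configured: `tiny` (7 plain conv blocks, 12/24/48
channels at strides 4/8/16 — the desk-scale workhorse), and standard
`resnet18` / `resnet101` residual layouts (blocks 2-4 at strides 8/16/32
with 128/256/512 and 512/1024/2048 channels) for architecture-faithful
shape and parameter accounting; `model_parameter_count()` reproduces the
single-18 < dual-18 < single-101 ordering of the full-size models. No
pretrained weights ship with the package; everything trains from seeded
random initialization.

Training follows the emulated protocol: patches sampled so that at least
half contain a labeled MF, the four-operation augmentation pipeline (color
jitter, Gaussian blur, pixel drop, right-angle rotation; spatial transforms
shared across stains, photometric ones drawn independently — the emulated
protocol does not say which choice its authors made), validation average
precision after every epoch, early stopping and checkpoint selection with
patience 5. `detector_config()` defaults to the protocol's AdamW learning
rate of 1e-4; `desk_detector_config()` is the tuned desk-scale schedule
(tiny backbone, 128 px patches, lr 1e-3, two-patch batches, 36 steps per
epoch, at most 13 epochs). The higher rate reflects the five-orders-smaller
model and the short schedule; with 1e-4 the compact model simply has not
converged within a desk-scale budget. Three optimization safeguards are
configurable. A burn-in (`min_epochs`, default 4) excludes the first epochs
from checkpoint selection and patience counting: validation AP from a
barely-trained model is noisy enough that a lucky early spike would
otherwise freeze a bad checkpoint. A divergence retry handles the rare run
that never discovers the objects: if the best validation AP stays below
`restart_floor` (default 0.35) after the full schedule, the model is
retrained once from a reseeded initialization and the better run by
*validation* AP is kept; both rules are applied identically to every model
and never consult test data. A linear learning-rate warmup is also
available but off by default — it delayed convergence more than it
stabilized it at this scale.

## Evaluation

Whole images are processed as overlapping 512 px tiles (50 px overlap, the
last tile clamped to the border: for a 1024 px side the origins are 0, 462,
512); per-tile detections above the score threshold are transferred to
global coordinates and deduplicated with one global IoU-based non-maximum
suppression (threshold 0.3; a center-distance variant exists). An optional
`edge_margin` discards detections hugging interior tile borders — they are
covered again by the neighboring tile. Average precision uses
center-distance matching at 7.5 um (consistent with the consensus radius;
an IoU criterion is available behind the same interface), ranked greedy
matching to the nearest unmatched ground-truth point and the all-point
interpolated precision-recall curve; a brute-force enumeration oracle
checks it exactly. The score threshold at inference defaults to a
deliberately low 0.05 so the ranked list retains low-confidence detections
for the PR curve; operating points for yes/no decisions (the latent
analysis) are instead calibrated per model as the F1-maximizing threshold
on validation images.

`run_experiment_grid()` trains every model on every training label set over
shared Monte-Carlo splits (70/15/15 by image, validation and test floored,
remainder to train) and evaluates each trained model's detections under
every evaluation label set, including the post-hoc-cleaned one; the result
is the machine-readable twin of a cross-validated mean +/- sd AP table.
Inference per test image is run once and re-scored per label set.

## Latent-space analysis

A compact mitosis classifier (tiny backbone, global average pooling, 48-d
features at desk scale) is trained with the same augmentation pipeline and
early stopping on validation loss; its classification layer is dropped and
the pooled features serve as the embedding. The analyzed cells — the
PHH3-assisted consensus points attributed to ground-truth cells — are
embedded with test-time augmentation, allocating the configured total
number of representations round-robin (with 308 cells and 2000
representations, six or seven each; the emulated analysis states only the
total, the allocation is a package decision, and the first copy is always
unaugmented). UMAP (n_neighbors 15, min_dist 0.1, single-threaded so the
seed pins the layout) projects once; every per-phase plot reuses the same
coordinates and varies only the coloring. A cell counts as detected under a
condition if more than half of that condition's cross-validation models
produced a detection within 7.5 um at their calibrated operating points.
"Three quartiles of the distribution" is interpreted as the 75%
highest-density region of a Gaussian-kernel 2-D KDE (normal-reference
bandwidth), returned as contour polygons; a convex-hull construction would
be the simpler alternative but tracks multimodal point clouds poorly.
Degenerate inputs (fewer than three distinct points) collapse to a point
region. The boundary-shift statistic is the distance between the
missed-cell region centroids of the two training conditions, computed per
mitotic phase group; the package's directional claim is that this shift is
larger for pro/prometaphase (where the mismatch cells live) than for
ana/telophase.

## Numerical choices and degenerate inputs

* All coordinates are 0-based pixel centers in the H&E frame; microns are
  converted via `mpp` at use sites only.
* Every random stream derives from one base seed through a string-keyed
  32-bit hash, making each image, rater, phase, epoch and augmentation
  draw independently reproducible.
* Metric conventions: 0/0 precision, recall and F1 are 0; AP with empty
  ground truth is explicitly undefined (`NA` with a note); a detector with
  no detections scores 0; zero-variance paired differences yield an
  undefined t statistic, reported as such.
* ICC is undefined when the between-target mean square vanishes; Fleiss'
  kappa when a single category is ever used. Both raise informative errors.
* The dart-throwing cell placer fails with an explicit message naming the
  separation constraint when the requested density cannot be packed.
* Large simulated datasets are cached as 8-bit rasters (1/255 quantization)
  so a 200-image study stays in memory; patches are dequantized on crop.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
the rater-study statistics on 20 images with 13 raters; replicate
directional checks on twenty 4-image studies; the detection grid on a
160-image study (tests) or 120-image study (acceptance script) with two
Monte-Carlo splits and three (tests) or one (script) training seeds; the
latent analysis on 16-120 images with two cross-validation detectors per
condition. These sizes were chosen so each stage completes in minutes on a
single CPU while leaving the directional effects far from the noise floor.

## Limitations

* The renderer is schematic. Passing tests demonstrate that the pipeline
  recovers the *informational* consequences of the stain mismatch; they say
  nothing about texture-level difficulty of real histology, stain
  variation, scanner artifacts, or real registration failure modes.
* Rater behaviour is Bernoulli per cell given the profile; real raters are
  correlated through per-cell difficulty, which the independent-draw model
  replaces by panel-level spread.
* The compact detectors are orders of magnitude smaller than production
  models; absolute AP values are not comparable to full-scale results, only
  the orderings across label conditions are meaningful.
* UMAP layouts are not comparable across implementations or seeds; the
  analysis therefore never interprets absolute projected coordinates, only
  within-layout differences between conditions.
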