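---
title: "Continuous fibrosis scoring from H&E images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous fibrosis scoring from H&E images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hecif)
```

## The problem

Bone-marrow fibrosis in myeloproliferative neoplasms (MPN) is graded on
reticulin-stained trephine sections using the semiquantitative WHO MF
scale (0–3). Reticulin silver stains are technically fragile: stain
intensity varies between laboratories, decalcified bone detaches during
processing, and the usable intertrabecular area shrinks accordingly.
`hecif` implements a reticulin-free alternative: a **continuous per-tile
fibrosis score** (CIF, Continuous Indexing of Fibrosis, in $[0,1]$)
predicted directly from routine H&E-stained images by a model trained
with **ordinal supervision** — the model never sees absolute grades, only
which of two tiles is more fibrotic.

The package covers the full supporting pipeline: a synthetic paired-stain
phantom generator with known ground truth, tissue masking and grid
tiling with the fat/bone composition filter, affine registration of
co-sectioned stain pairs from their tissue masks, channel-wise histogram
equalisation, slide-level stain/tissue QC in RGB and CIELAB, and a
subsampling analysis of fibrosis heterogeneity and biopsy adequacy.

## The ranking model

Severity is learned from ordered tile pairs. Given teacher labels
$y_i \in [0,1]$ (on phantoms, the latent-field ground truth; in general
any per-tile teacher), training pairs $(i, j)$ are drawn with
$y_i - y_j \ge \delta$ (default $\delta = 0.1$). A shared scoring
function $f$ is fitted by minimising the pairwise logistic (RankNet)
loss

$$\mathcal{L} = \sum_{(i,j)} \log\left(1 + e^{-(f(x_i) - f(x_j))}\right),$$

with a margin hinge available as an alternative. Raw scores are mapped
to the CIF scale by min–max calibration over the training scores,
clipped to $[0,1]$: the least fibrotic training tile anchors 0, the most
fibrotic anchors 1. The slide-level score is the arithmetic mean of the
per-tile scores of analysable tiles.

**Architecture.** The scorer is a compact feed-forward ranking network.
Each tile is reduced to a $p \times p$ grid of pooled descriptors
(default $p = 4$); every cell contributes its mean *and* its standard
deviation per colour channel ($6p^2 = 96$ features), which are
standardised and passed through one $\tanh$ hidden layer (16 units) to a
scalar. Optimisation is Adam on minibatches of pairs, 60 epochs, with
all randomness (pair sampling, initialisation, shuffling) governed by a
single seed. Two representational choices matter and were made
deliberately:

* **Dispersion features.** Per-tile histogram equalisation (below) maps
  every channel onto the full 0–255 range, so global block *means* carry
  almost no between-tile density information afterwards. The per-block
  standard deviation channel keeps local fibre texture visible to the
  model regardless of that normalisation.
* **Coarse pooling.** Fibre density — the severity signal — is a
  low-frequency statistic. A $4\times4$ grid is enough to carry it,
  while finer grids multiply parameters and, at desk-scale training-set
  sizes (hundreds of tiles), lead the network to memorise tile noise:
  in our phantom experiments validation accuracy *dropped* as the grid
  was refined past $8\times8$.

The backbone is intentionally pluggable: on real slides a deeper
convolutional scorer can fill the same role behind `train_ranking_model()`
without changing the pairing, calibration or evaluation machinery.

**Prediction accuracy** is operationalised as $\delta$-separated
pairwise concordance (`pairwise_prediction_accuracy()`): the fraction of
validation pairs with label gap $\ge \delta$ whose predicted scores are
strictly concordantly ordered. This is the natural accuracy for a model
trained only on orderings; $\delta$ is reported alongside.

## The phantom generator

Every downstream stage is testable against `generate_phantom()`, which
renders an H&E-like and a reticulin-like image of the same virtual
section with full ground truth:

* a **latent fibrosis field** in $[0,1]$ — constant, or a smoothed
  Gaussian random field with stated correlation length and amplitude;
* **fibre texture** drawn as curvilinear random-walk strokes (dark in
  the pseudo-reticulin, eosinophilic in the pseudo-H&E). Candidate
  stroke seeds are placed uniformly in stroma and accepted with
  probability equal to the local field value, so for a fixed seed a
  higher severity accepts a superset of strokes and rendered density is
  monotone in severity by construction;
* **bone trabeculae** (pale rimmed blobs) and **fat vacuoles** (white
  ellipses), disjoint by construction so composition fractions are
  exactly computable from the masks;
* a **known affine misalignment** between the stain frames
  (rotation/scale about the canvas centre plus translation), applied by
  rendering the reticulin frame through the exact inverse warp;
* **per-slide stain drift** — one global additive shift per channel per
  stain, with configurable standard deviation per arm — matching the
  slide-level granularity at which the QC compares dominant colours;
* **bone-loss artefacts**: each trabecula in the pseudo-reticulin
  rendering keeps only the $(1-f)$ fraction of its pixels nearest its
  centroid (the rim erodes first, as physical detachment does).

Default geometry is a 2048 px canvas at 0.22 µm/px, so a 512 px tile
spans ≈113 µm. Desk-scale experiments in the tests use the same physical
tile span at reduced resolution (128 px at 0.88 µm/px): severity is
carried by fibre *counts* per tile, so holding the physical span fixed
preserves the signal-to-noise of the severity signal while cutting
runtime 16-fold.

What the phantom does **not** emulate: nuclei, megakaryocytes and other
cellular detail; scanner-specific artefacts; stain deconvolution
subtleties; deformable (non-affine) section distortion. Passing tests
therefore demonstrate that the pipeline machinery is correct and that
the model recovers a planted ordinal texture signal — not that any
particular accuracy transfers to clinical material.

## Tiling and the analysability filter

Tiles are laid on a non-overlapping grid anchored at the image origin
(0-based, half-open extents); partial edge tiles are discarded. A tile
is kept when its tissue fraction reaches `min_tissue_fraction`
(default 0.5). The **analysability filter** retains exactly the tiles
with fat fraction $< 0.50$ and bone fraction $< 0.01$, both strict, so
boundary values are excluded; the filter is idempotent and is checked
against brute-force enumeration in the tests.

Tissue masks come from classical thresholding (luminance below
near-white background, or visible chroma) followed by morphological
closing, hole filling — fat vacuoles inside tissue belong to tissue —
and small-object removal. The masking function is a pluggable interface:
a learned segmenter can replace it without touching the rest of the
pipeline.

For the rank-recovery experiments the training tiles are *interior*
tiles (tissue fraction ≥ 0.9, low fat). The phantom's ground-truth label
is the mean of the latent field over the whole tile footprint, including
any background or fat the footprint covers, while rendered fibre density
scales with the *stroma* actually present — so composition-heavy tiles
carry labels that conflict with their visible evidence. Interior tiles
remove that label noise from the training signal; the analysability
filter (a weaker condition) remains the deployment-time gate.

## Registration

The affine between a reticulin slide and its H&E counterpart is
estimated from the binary tissue masks alone, never from intensities:
moment-based initialisation (centroid translation, principal-axis
rotation, isotropic scale from the area ratio) followed by Nelder–Mead
refinement of (rotation, log-scale, translation) maximising mask IoU.
Numerical choices:

* the principal axis is defined modulo 180°, and boundary clipping can
  bias it, so a small rotation grid (±6° in 2° steps around both
  orientations) is scanned before refinement and the best-overlap
  candidate kept;
* masks longer than 384 px on a side are subsampled for the refinement
  objective only — moments and the final reported IoU stay at full
  resolution;
* a final IoU below 0.5 flags the registration as `failed` rather than
  erroring, so cohort runs can report rather than abort.

Matched tiles are produced by mapping source tile centres through the
transform and reading the destination tile at the mapped centre without
resampling, preserving native H&E texture for training.

## Histogram equalisation

`equalize_channels()` implements plain global per-channel equalisation:
each channel is remapped by its own cumulative distribution to span
0–255, with the lowest occupied level anchored at 0. The map is
monotone (rank-preserving), idempotent up to one quantisation level,
and invariant to global additive shifts that do not clip — which is
exactly the slide-level stain-drift model the phantom implements. A
constant channel maps to mid-scale 128 by convention. Statistics are
computed per tile by default; computing them per slide instead is a
caller decision (equalise the slide image before tiling).

## Quality control

Three slide-level axes:

1. **Stain colour variation.** The dominant tissue colour per slide is
   the modal bin of a 16-level-per-channel quantisation (deterministic;
   ties resolve to the lowest bin; the mean of the pixels in the modal
   bin is returned so uniform regions yield their exact colour).
   Dominant colours are compared across a cohort in RGB and in CIELAB
   (sRGB → XYZ under D65/2° → L\*a\*b\*, implemented from the standard
   formulas and checked against an independent oracle at 1e-6).
   Cohort dispersion is the trace of the per-arm covariance; arms are
   compared by a seeded bootstrap of the trace ratio. The bootstrap is
   a pragmatic dispersion test chosen for transparency — it is this
   package's choice, not a claim about any published analysis.
2. **Bone area**: pixel count × (mpp/1000)², exactly quadratic in mpp.
3. **Analysable tile count**, optionally restricted to an annotation
   mask (tile-centre-inside rule).

Paired per-sample comparisons use an exact Wilcoxon signed-rank test at
small n.

## Subsampling and heterogeneity

`deviation_curve()` emulates shrinking a biopsy: at each area fraction
(default $2/15, 4/15, \dots, 10/15$ of the analysable tiles), a centre
tile is drawn uniformly and the region grown by repeatedly adding the
analysable tile nearest the centre (Euclidean distance between tile
centres, ties by tile index) until `round(fraction × N)` tiles are
included — a deterministic realisation of "expand around a random
centre to a target area ratio", measured in tile counts because tiles
are the support of the CIF map. Each draw records the subsample mean
CIF and its absolute deviation from the whole-sample CIF. A sample is
called **heterogeneous** when any smallest-fraction subsample deviates
by strictly more than 0.1; a deviation of exactly 0.1 stays homogeneous.
Default 20 draws per fraction, seeded.

On spatially correlated phantom fields the mean maximum deviation
decreases as the subsampled fraction grows — the qualitative
biopsy-adequacy trend — and the tests assert this at cohort level
(n = 12 slides, 20 draws) within one standard error.

## Problem sizes and determinism

The test-suite experiments run on reduced geometries chosen to keep the
severity signal well above rendering noise: registration sweeps on
896 px canvases with margined tissue (so ±100 px translations never push
tissue off-canvas), rank recovery on ≈500 tiles of 128 px at 0.88 µm/px
from 54 constant-severity phantoms with a 25% random holdout and three
training seeds, subsampling cohorts of 12 random-field phantoms, and QC
discrimination on 20 replicate cohorts with a 5× stain-drift and 30%
bone-loss handicap on the pseudo-reticulin arm. Every stochastic step —
phantom rendering, pair sampling, weight initialisation, bootstrap,
subsample draws — is governed by explicit seeds, and identical seeds
reproduce byte-identical score tables end to end.

## Known limitations

* The phantom's fibre texture is schematic; stroke geometry is a free
  modelling choice, documented, not claimed to match real reticulin
  morphology.
* Only a single global affine is estimated; deformable distortion
  between co-sectioned slides is out of scope.
* The default scorer is a small dense network suited to desk-scale
  texture; clinical-resolution slides would warrant a convolutional
  backbone behind the same interface.
* CIF calibration is relative to the training cohort's score range;
  scores are comparable within a trained model, not across independently
  trained models without a shared reference.
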