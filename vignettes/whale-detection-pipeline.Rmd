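---
title: "Tile-based whale detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based whale detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whaletiles)
```

## The problem

Large whales are visible from very high-resolution (sub-metre) satellite
imagery, but they are rare: in an operational survey a handful of whale
tiles hides among tens of thousands of tiles of open water (imbalances on
the order of 690 whale vs ~40,000 water tiles are typical). Manual
annotation at basin scale is infeasible, so the practical goal is
*semi-automated triage*: a classifier that confidently eliminates empty
ocean and hands a short, ranked candidate list to an expert.

whaletiles implements that pipeline end to end. Fine-resolution aerial
imagery (~2 cm ground-sample distance, GSD) supplies abundant labelled
whale examples; it is down-sampled to the satellite sensor's 31 cm GSD so a
model trained on it transfers to satellite scenes it has never seen.
Satellite multispectral bands (124 cm) are pansharpened against the 31 cm
panchromatic band, reduced to RGB, and split into 32 x 32-pixel tiles
(98.4 m^2 at 31 cm) that form the classification unit.

## Pipeline stages

1. **Scene preparation** — `bilinear_downsample()` resamples aerial scenes
   to the target GSD (output dimensions `round(dim * src/target)`);
   `gram_schmidt_pansharpen()` fuses multispectral and panchromatic rasters;
   `extract_rgb()` keeps the visible bands, where whale spectral response is
   concentrated.
2. **Tiling and labelling** — `tile_scene()` enumerates tiles row-major
   from a configurable grid origin (0-based, half-open intervals; trailing
   partial strips are dropped rather than padded, so no tile carries
   invented content); `assign_labels()` applies the retention rule: a tile
   is a whale tile when it holds at least 20% of some whale's pixels,
   water when it holds none, and *excluded from both classes* when it holds
   only a sliver (a fraction in (0, 0.2), recognizable only in context).
   The boundary is inclusive at 0.20, and the denominator is the whale's
   total pixel count, not the tile area.
3. **Dataset assembly** — stratified 90/10 and k-fold splits
   (`make_folds()`), water-pool subsampling (`subsample_class()`), and the
   balanced whale:water subset for the classical baselines
   (`balanced_subset()`).
4. **Training** — a two-class head on a configurable backbone, trained by
   SGD with momentum 0.9 under a step-decay learning rate
   (`lr_schedule(base, e) = base * 0.1^floor((e-1)/7)` by default), with a
   weighted random sampler whose inverse-class-frequency weights make the
   expected whale share of every batch 1/2. Each epoch is evaluated on the
   held-out set and checkpointed; `select_best_epoch()` takes the F1 argmax
   (earliest epoch on ties).
5. **Evaluation** — the survey convention scores *water as the positive
   class*: precision is the purity of model-classified water, recall the
   fraction of true water recovered. The whale-detection false-positive
   rate (water tiles flagged whale over all water tiles) is a second,
   deliberately separate convention reported side by side. Undefined
   metrics from zero denominators surface as explicit `NA` markers, never
   silent zeros, so degenerate folds stay visible in `fold_report()`.
6. **Triage** — `triage()` ranks satellite tiles by whale probability and
   exports everything above a review threshold with scene coordinates.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| tile side | 32 | px | classification unit; 98.4 m^2 at 0.31 m/px |
| retention threshold | 0.20 | fraction of whale | inclusive boundary; slivers excluded from both classes |
| learning rate | 6e-4 (deep), 0.02 (smallnet quickstart) | — | step-decayed x0.1 every 7 epochs |
| momentum | 0.9 | — | standard SGD pairing |
| epochs | 24 (deep), 12 (quickstart) | — | per-epoch checkpoints; best epoch selected post hoc |
| batch size | 4–32 | tiles | small batches plus weighted sampling |
| decision threshold | 0.5 | p(whale) | ties go to water so a degenerate model does not flood the review queue |
| HOG | 8 px cells, 2x2 blocks, 9 unsigned bins | — | canonical detector configuration; L2-Hys normalization |
| ridge alpha / C-SVC C | 1 / 1 | — | baseline operating points; RBF kernel with scale-heuristic bandwidth |

Open design points were settled as follows. The decay factor of the
learning-rate schedule is 0.1, the conventional step-decay value. The
optimizer is SGD with momentum (the standard pairing for a stated momentum
parameter). Input normalization uses per-dataset channel statistics when
training from random initialization; pretrained-weight normalization
constants would apply only with pretrained backbones, which this package
does not ship — requesting `pretrained = TRUE` is an explicit error, never
a silent fallback to random weights. Baselines consume HOG features of the
native 32-px tiles: interpolation to 224 px adds no gradient information.
Fold assignment defaults to the frame level; `unit = "individual"` is
offered because duplicate frames of one whale in both train and test leak
information.

## The synthetic-data generator

No open, deposited imagery exists for this problem (aerial survey footage
is proprietary, satellite scenes are commercial), so the package ships a
seeded scene generator that every stage is tested against.

A scene is a reflectance-like `[0, 1]` raster: a low-frequency swell field,
directional wave streaks, fine pixel noise, and Bernoulli whitecap speckle
whose rate grows with an ordinal sea state 0–5. Texture scales are
*physical* (swell patches ~6 m, streak wavelengths 2.5–5.5 m), so aerial
scenes down-sampled to 31 cm match native satellite texture statistics —
the property that makes aerial-to-satellite transfer meaningful. Whales
are anti-aliased rotated ellipses (length:width about 5:1) with a
perpendicular fluke lobe, darker than the surrounding water by a
configurable contrast margin (default 0.15, with per-pixel jitter);
their drawn length interval defaults to 7–9 m ("minke-like") for training
scenes and 12–16 m ("right/humpback-like") for satellite test scenes —
generator knobs, not biological claims. Each instance carries a pixel
mask; duplicate frames of one individual share an `individual_id`.
Multispectral scenes emit a 4x-coarser band stack plus a fine pan band,
mirroring the 124 cm / 31 cm sensor pairing. Whitecap fraction is
non-decreasing in sea state; above roughly Beaufort 4 the speckle density
approaches the regime where visual whale detection breaks down.

What the generator does **not** emulate: radiometric sensor physics, sun
glint, cloud, swell refraction, whale surfacing behaviour, or the texture
of real ocean colour. Passing tests therefore demonstrate that the
pipeline's *machinery* is correct and that its ordering properties (deep
model over HOG baselines, degradation with falling contrast and rising sea
state) hold on controlled data — they are not evidence about accuracy on
real WorldView-3 imagery, which requires proprietary data this package
cannot ship.

## Numerical choices

- **Gram-Schmidt pansharpening** simulates a coarse pan as the weighted
  band sum (uniform weights by default), orthogonalizes the bands with the
  simulated pan as first component, substitutes the true pan, and inverts.
  The substituted pan's statistics are matched *on the multispectral grid*:
  after block-averaging, its mean and standard deviation equal the
  simulated pan's. Matching at the coarse grid rather than against the
  upsampled component keeps the sharpened product spectrally consistent
  (block-averaging the output reproduces the input bands to RMSE well
  under 0.02 at every sea state) even when the pan carries single-pixel
  speckle invisible at 124 cm. Degenerate inputs (zero-variance pan or
  simulated pan) are errors, not warnings.
- **Mask resampling** uses exact area-weighted averaging via a summed-area
  table (the SAT of a piecewise-constant raster is piecewise bilinear, so
  interpolating it at fractional footprint corners is exact). Masks become
  fractional-coverage rasters at 31 cm, which keeps the 20% retention rule
  meaningful after down-sampling.
- **Tile enlargement** (32 to 224 px) is bilinear by default with
  nearest-neighbour selectable.
- **Ridge baseline** solves the penalized normal equations in closed form;
  with `alpha = 0` and collinear descriptors the system is rank-deficient
  and the minimum-norm (pseudo-inverse) solution is used.
- **Determinism**: one master seed fans out to scene generation, splits,
  initialization, and batch sampling; identical configurations reproduce
  bit-identical manifests and (up to platform floating-point behaviour)
  identical metrics. All scene generation runs on a private RNG stream and
  restores the caller's random state.

## The training engine

No deep-learning framework is available to R in this package's dependency
footprint, so whaletiles ships its own compact convolutional engine:
convolutions are lowered to BLAS matrix products (im2col), with batch
normalization, max/average pooling, global average pooling, residual
blocks, and dense concatenation blocks, verified against numerical
gradients. The standard deep backbones (resnet18/34/152, densenet) are
constructed with their usual shapes and a 2-logit head; `smallnet` — three
convolution/pool stages and a linear head — is the backbone the shipped
experiments train, because it reaches the synthetic tasks' performance
ceiling on one CPU in minutes.

## Problem sizes in the shipped experiments

The quickstart recipe trains on 36 aerial scenes (24 with a whale imaged
twice, 12 water-only; 288 px at 7.75 cm GSD, down-sampled 4x) giving
roughly 50 whale and 80 water training tiles, and evaluates on 20
satellite scenes (~20 whale and ~150 water tiles) — sizes chosen so the
whole recipe, including both classical baselines, completes in about a
minute on one CPU while still exercising every pipeline stage at a
class imbalance the weighted sampler has to correct. The hard-condition
comparison reruns the identical recipe at sea state 3 with the contrast
margin lowered to 0.05 (the generator's contrast default is explicitly a
test-hardness knob, not a fidelity claim).

## Known limitations

- Reported performance on synthetic scenes does not transfer to real
  imagery claims; the generator's whale/water contrast statistics are not
  calibrated against any sensor.
- Geo-referenced raster I/O is limited to PNG with a JSON sidecar carrying
  GSD and provenance; geodetic reprojection, orthorectification and
  atmospheric correction are out of scope.
- The engine is CPU-bound; the deep backbones are provided for structural
  fidelity and inference-scale use, not full-scale training.
- Overlapping tile grids (`stride_px < tile_px`) are supported at tiling
  level, but the shipped recipes use disjoint grids.
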