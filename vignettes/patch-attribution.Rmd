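---
title: "Exact patch attribution by mean-logit aggregation: model, saliency and evaluation"
author: "patchlogit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact patch attribution by mean-logit aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchlogit)
```

## The model

`patchlogit` implements a self-explainable multi-label image classifier.
An `S x S` grayscale image (intensities in `[0, 1]`) is cut into a
`P x P` grid of non-overlapping `p x p` patches, `p = S / P`. A single
shared encoder `f` maps each patch `x_i` independently to a vector of `C`
raw class scores (logits), `z_i = f(x_i)`. The image-level logit is the
fixed arithmetic mean

    Z = (1/P^2) * sum_i z_i,

and the class probabilities are `yhat = sigmoid(Z)`, with the sigmoid
applied **after** averaging so that no patch's influence is squashed before
aggregation. Because the aggregation is a fixed mean — not attention, not a
learned pooling — the contribution of patch `i` to class `k` is exactly
`z_i[k] / P^2`. Nothing can affect the prediction without appearing in some
patch's logits; this is an architectural guarantee, not a post-hoc
approximation. The model is the fixed-mean special case of multiple
instance learning: each patch "votes" for or against each class, with
signed strength.

Two attribution variants are provided. The *raw* variant visualizes `z_i`
directly. The *scaled* variant multiplies elementwise by the image-level
probabilities, `zhat_i = yhat * z_i`, injecting a limited amount of global
context while preserving each logit's sign (probabilities are positive).

Assumptions worth stating: every class must be decidable from local
evidence at the patch scale. Findings that require integrating widely
separated image regions (beyond `p` pixels) are outside what the mean of
independent patch scores can represent; that is the price of the exact
decomposition.

### The encoder contract

The encoder is pluggable. It must be deterministic given its parameters,
produce `C` logits for one `p x p` patch, and be applied identically to
every patch — no positional inputs, no cross-patch state. Two trainable
families are bundled:

* `mlpEncoder()` — flattened pixels, one ReLU hidden layer. Inputs are
  centered by a fixed `-0.5` shift.
* `cnnEncoder()` — one valid square convolution (default `9 x 9` window,
  stride 2) with ReLU, then a dense logit head over all positions and
  filters. Each patch is centered by its own mean intensity before the
  convolution, which removes the smooth background-brightness nuisance that
  otherwise dominates the first layer; the patch mean re-enters the dense
  head as one extra feature so absolute brightness remains visible. This
  centering scheme is an encoder-internal choice and does not alter the
  contract.

`funEncoder()` wraps arbitrary functions (analytic references,
instrumented encoders for counting forward passes in tests).

## Saliency maps

With offset `o = p` the saliency map for class `k` is block-constant:
every pixel of patch `i` holds `z_i[k]` (or `zhat_i[k]`). For a raw-source
map the pixel mean equals `Z[k]` exactly — attribution is conservative by
construction.

Smoothing trades computation for resolution. For each shift `(dy, dx)` in
`{0, o, 2o, ..., p-o}^2` the patch grid is displaced over the zero-padded
image, with one extra row and column of border patches so that **every**
pixel is covered by exactly one patch in every shifted grid; one forward
pass per shift scores the displaced grid, the block map is read off in
original coordinates, and the `(p/o)^2` maps are averaged pixelwise with no
border renormalization. Consequences that the test suite asserts:

* `o = p` reproduces the block map exactly with a single forward pass;
* `o = 1` costs `p^2` forward passes;
* an input-ignoring encoder yields a spatially constant smoothed map for
  every offset (no border artifacts from the padding convention);
* every smoothed pixel lies within the range of the values assigned by the
  contributing shifted grids.

For the scaled source, the probabilities used for scaling are recomputed
for each shift from that shift's own forward pass (the core, non-border
patches — exactly the forward pass of the translated image), since scaled
logits are defined per forward pass.

Shift direction is canonical: content moves down-right; grids are anchored
top-left. One convention had to be fixed for bit-reproducibility; this is
the one used everywhere.

`renderOverlay()` writes a diverging overlay: red for evidence supporting
the class, blue against, near-zero values near-transparent, color scale
symmetric about zero and anchored at the per-map `max |value|` (per-image
anchoring keeps zero visually neutral regardless of the map's dynamic
range).

## Localization evaluation

The protocol evaluates how well a saliency map points at and covers the
ground-truth lesion mask.

**Hit rate (pointing game).** For each case with a non-empty ground-truth
mask, find the maximum-saliency pixel; score 1 if it lies inside the mask.
Ties at the maximum are frequent on block-constant maps, so the tie rule
matters and is pinned: the smallest row-major pixel index (top row first,
then left to right) wins. A permissive mode (hit if *any* maximal pixel is
inside) exists but is off by default. Label-positive cases without a mask
are excluded from the denominator.

**mIoU over TP/FP/FN.** Saliency is binarized by a strict `value > t`
threshold (so a threshold at the maximum yields an empty mask). A case is
TP (positive label, non-empty predicted mask), FP (negative label,
non-empty mask), FN (positive label, empty mask) or TN (negative label,
empty mask). TPs contribute `IoU(prediction, ground truth)`; FPs and FNs
contribute 0 — one of the two masks is empty, so the overlap is zero and
dropping those cases would overstate performance precisely where reliable
feedback matters most; TNs are excluded. `tp_only` mode averages TPs
alone.

**Threshold tuning.** One threshold per label, chosen on validation cases
to maximize the TP/FP/FN mean IoU. The search grid is the set of quantiles
(default 100) of the pooled validation saliency values for that label,
deduplicated, plus a `-Inf` sentinel; quantile grids adapt to any saliency
scale. Ties resolve to the larger threshold.

**Classification metrics.** AUROC is computed from midranks
(Mann-Whitney; ties count one half). Youden thresholds maximize
sensitivity + specificity over midpoints between sorted unique scores,
ties toward the larger threshold; single-class labels are skipped with a
warning.

**Uncertainty.** Percentile bootstrap: resample cases with replacement
(same `N`), recompute, report the 2.5%/97.5% quantiles. Percentile rather
than BCa intervals: simple, seed-reproducible, and adequate at the case
counts involved. Resamples on which a metric is undefined (e.g. a
single-class resample) are skipped and counted. The default of 100,000
resamples matches large-scale practice; desk-scale runs use 1,000-10,000.

## Training

Training is weakly supervised: only image-level labels, never masks. The
loss is multi-label binary cross-entropy between `sigmoid(Z)` and the
label vector, computed on the global outputs only (no per-patch auxiliary
losses; identical patches therefore receive identical gradients through
the mean — asserted in the tests). Optimization is AdamW (decoupled weight
decay on weight matrices, none on biases) under a one-cycle schedule:
linear warmup to the peak rate over the first 5% of steps, cosine
annealing to 1% of the peak. The cosine shape and the weight-decay default
(`1e-4`) are this package's choices, documented rather than asserted.

Augmentation follows the standard radiograph recipe: random square crop
covering 50-100% of the area resized back to `S`, rotation within ±5°
(bilinear, zero fill), brightness factor in `[0.7, 1.3]` with clipping to
`[0, 1]`. Augmentation is exercised by its own tests; the synthetic
recovery study below trains without it, because phantoms are i.i.d. draws
from the generative model itself and augmentation only slows convergence
there.

The default configuration (`trainConfig()`) keeps batch size 16 and peak
rate `1e-4` — sensible for a large pretrained backbone. The desk-scale
studies use a higher peak (`3e-2`) and batch 32, appropriate for the small
randomly initialized encoders trained here.

## The synthetic phantom study

`phantomSpec()` defaults define the package's study conditions, chosen
once as a realistic desk-scale analogue of a chest-radiograph localization
dataset:

* 128 x 128 images, an 8 x 8 grid of 16 x 16 patches — the published
  grid layout at quarter scale;
* a smooth elliptical "thorax" gradient (intensity 0.12-0.55) with
  Gaussian pixel noise (sd 0.05);
* three labels with locally distinguishable lesion types: a bright disk
  (+0.45, radius 8-14 px), a dark ellipse (-0.42, radius 10-18 px) and a
  thin bright bar (+0.40, half-length 12-20 px). Contrasts have distinct
  magnitudes so overlapping lesions never cancel exactly and every mask
  pixel provably differs from its lesion-free counterfactual;
* two to three lesions per positive label, prevalence one half per label;
  the resulting mean ground-truth mask area fraction is about 0.05, which
  is also the chance floor for the pointing game (verified by simulation
  against uniform-random saliency);
* an optional shortcut mode stamping a bright corner marker correlated
  (strength `rho`) with one label — the laterality-marker trap in
  miniature; `rho = 1` makes the marker a perfect label proxy.

Each phantom is returned with its lesion-free counterfactual (same
background, same noise), giving an exact localization ceiling: the oracle
map `|image - counterfactual|` hits every lesion by construction.

What the phantoms do **not** emulate: anatomical texture, projection
geometry, inter-reader mask variability, label noise, global dataset
biases (vendor post-processing, exposure differences). Passing the
synthetic study therefore demonstrates that the architecture, training
loop and evaluation protocol are correctly wired and that the mechanism
recovers localized evidence from image-level labels — not that any
particular clinical performance level would be reached on real
radiographs.

### Study design and problem sizes

The recovery study generates `n = 2000` phantoms (1600 train / 200
validation / 200 test), trains the convolutional encoder (24 filters,
9 x 9 window, stride 2) for 35 epochs, and evaluates held-out label-mean
AUROC plus the pointing-game hit rate of shift-smoothed raw maps at
`o = 4`. These sizes keep the full study in CPU minutes while leaving
clear margins to the acceptance bands.

Smoothed rather than block maps are evaluated deliberately: on a
block-constant map the deterministic argmax tie rule always selects the
top-left pixel of the best patch, which for a compact lesion centered in a
patch lies outside the mask — a property of the tie-break convention, not
of localization quality. Smoothing at `o = 4` breaks the ties by moving
the maximum into the interior of the consensus region. The `o = p` block
map hit rate is reported by the acceptance machinery alongside the
smoothed one if you care to compare.

The shortcut study sets lesion contrast to zero and `rho = 1`, so the
corner marker is the only signal. The trained model's saliency argmax then
falls in the marker-containing patch for essentially all positive images —
the architecture surfaces the shortcut rather than hiding it, which is the
practical point of exact attribution.

## Numerical choices and degenerate inputs

* Sigmoid is computed in the branch-stable form; `|Z|` up to ~745
  underflows cleanly to 0/1 rather than overflowing.
* Global logits use compensated column means (`colMeans`); the
  decomposition identity is asserted to `1e-5` but holds to machine
  precision at the grid sizes used.
* Non-divisible `S / p` is a hard error, never implicit padding — silent
  padding would corrupt the attribution geometry.
* Non-finite patch logits abort aggregation naming the offending patch.
* An empty ground-truth mask makes the hit indicator undefined (error),
  and a both-empty mask pair makes IoU undefined; category routing
  (`caseCategory`) is the supported path for empty predictions.
* RLE masks use column-major runs with a leading zero-run (an empty mask
  is `[S*S]`, a full one `[0, S*S]`); PNG masks are 0/255. Both codecs
  round-trip bit-exactly and are cross-checked against each other.
* All randomness flows from one top-level seed through named sub-streams
  (`deriveSeed`), so data generation, initialization, training and
  bootstrap are individually reproducible.

## Known limitations

* Classes requiring global context (relations between distant regions)
  are architecturally out of reach; the saliency for such a class would be
  diffusely spread rather than localized.
* Attribution is spatial only: the maps say *where* evidence sits, not
  *which* visual concept inside a patch produced it.
* Globally acting biases shift all patch logits together and are not
  isolated by patch-level attribution.
* The bundled encoders are deliberately small; the encoder contract
  accepts any stronger drop-in backbone.
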