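---
title: "Multi-target neck ultrasound segmentation: models, loss and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target neck ultrasound segmentation: models, loss and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transverse neck ultrasound shows the thyroid gland surrounded by structures
that are easily confused on B-mode imagery: the trachea, the esophagus, the
carotid artery, and — inside the gland — nodules and intra-thyroid vessels
whose echo patterns are nearly identical ("NoV", nodules-or-vessels, treated
as one class). Segmenting all six classes (background included) per frame is
the gateway to 3-D visualization of a freehand sweep: stacked per-frame label
maps become a labelled volume whose per-class surfaces show the spatial
relations between a nodule, the vessels and the surrounding organs.

Ultrasound makes this hard: multiplicative speckle, low contrast, small
structures. `sonoseg` addresses it with three ingredients on top of a nested
U-Net (U-Net++) encoder–decoder:

* a **pyramid pooling module (PPM)** on the deepest encoder feature, which
  average-pools the map to several grid sizes (default 1, 2, 3 and 6),
  reduces each pooled map to `C/N` channels with a 1×1 convolution, upsamples
  bilinearly and concatenates everything with the input — injecting global
  and sub-region context while exactly doubling the channel count;
* **attention gates (AG)** on the decoder skip bundles: a per-pixel
  coefficient `Q = sigmoid(BN(conv1x1(ReLU(BN(conv1x1(x)) + BN(conv1x1(g))))))`
  computed from the skip bundle `x` and the upsampled deeper decoder feature
  `g`, multiplied into `x` to suppress background responses;
* the **Lovasz-Softmax loss**, a convex surrogate of the per-class Jaccard
  loss, in place of cross-entropy.

## The Lovasz-Softmax loss

For class `c`, the discrete Jaccard loss of a prediction is
`1 - |P_c ∩ G_c| / |P_c ∪ G_c|` (with `0/0 = 1` for the index). Viewed as a
set function of the *mispredicted pixel set* it is submodular, so its Lovasz
extension is its tight convex closure on `[0,1]^p`: sort the per-pixel errors
`E_i(c)` (`1 - f_i(c)` on pixels of class `c`, `f_i(c)` elsewhere, with `f`
the softmax probabilities) in decreasing order, and take the inner product
with the forward differences `g_i` of the discrete loss over the growing
prefix sets. The package computes `g` with O(p) cumulative intersection and
union counts; tests verify this against a literal prefix-set evaluation and
— exhaustively for up to 4 pixels and 3 classes — that the extension
coincides with the discrete loss at every one-hot vertex. The training loss
averages the extension over all `|C|` classes (an option restricts the
average to classes present in the batch, useful when rare classes are
missing from a mini-batch). Gradients with respect to the network scores are
analytic (the extension is piecewise linear in the errors; ties in the sort
pick one valid subgradient, deterministically by pixel index) and are
checked against finite differences.

By default the error vectors are built from all pixels of a batch flattened
together (batch-level Jaccard), matching the way the surrogate is commonly
trained; a per-image mode is available. An optional cross-entropy term
(`loss = "lovasz+ce"`) can be mixed in as a warm-start aid; the default is
the pure surrogate.

## Architecture

The backbone is the nested U-Net grid `X[i, j]` (depths 0–4, columns 0–4):
every node receives all same-depth predecessors plus the bilinearly
upsampled, 1×1-convolved deeper node, each node being two 3×3 convolutions
with batch normalisation and ReLU. Downsampling is 2×2 max-pooling. Widths
default to (32, 64, 128, 256, 512); a `tiny_widths()` preset
(8, 16, 32, 64, 128) keeps CPU experiments tractable. Decoding modes `L2`,
`L3`, `L4` read a single head off `X[0, j]`; deep supervision (`DS`) trains
all four heads with an unweighted sum of their losses and averages their
softmax outputs at inference (`ds_head_combine = "last"` reproduces the L4
head). Where the wiring was genuinely open we chose: PPM only after the
deepest encoder node, fused back to the encoder width with a 3×3
convolution; AG applied to the outermost decoder column by default (the
nested inner nodes' pairing is under-determined; `ag_full_grid = TRUE` gates
everything); bilinear resampling throughout; BN placed as the formula order
implies, with the ReLU after the additive join. Disabling PPM and AG
recovers a plain U-Net++ — verified by transplanting weights into an
independent naive-loop reference implementation and comparing outputs.

All tensor work runs on a package-internal reverse-mode autodiff engine:
an R tape over C++ kernels (im2col convolution through BLAS, pooling,
bilinear resize, channel-wise BN statistics). This keeps the package
self-contained and every gradient testable against finite differences.

## Synthetic phantoms: what they emulate, and what they do not

The phantom generator exists so that every stage is testable without
clinical data. Each frame is built from a piecewise-constant echogenicity
map with a fixed painting order (background → thyroid → NoV → trachea →
esophagus → carotid): a bright thyroid crescent wrapping an anechoic
trachea with a bright rim, 1–3 hypoechoic NoV ellipses constrained to the
thyroid support (an invariant the tests check), a small esophagus disc
beside the trachea and an anechoic carotid disc; geometry is jittered per
seed. Texture follows the fully-developed-speckle approximation:
i.i.d. multiplicative gamma noise with mean 1 (shape 4 by default, so the
noise standard deviation is 50% of the signal — strong, deliberately) and a
Gaussian point-spread blur (sigma 1.5 px). Sweeps cut 2-D cross-sections
from 3-D ellipsoids at uniform slice spacing, so reconstruction accuracy can
be compared with analytic volumes.

These phantoms reproduce the *structure* of the task — six classes, correct
topology, speckle, low contrast, class imbalance — but not acoustic physics:
no attenuation shadows, no refraction, no anisotropy, no probe motion. A
model that segments phantoms well has demonstrated that the loss,
architecture and training loop work; it has demonstrated nothing about
clinical performance.

## Training recipe and problem sizes

The default `train_config()` is the published-style recipe: Adam
(`beta1 = 0.9`), learning rate `1e-4` multiplied by 0.9 at epochs 100 and
150, batch size 16, 300 epochs, 256×256 inputs, Lovasz-Softmax loss. The
validation split (10% of training data) selects the checkpoint by mIOU;
early stopping is off by default.

For the CPU-scale experiments shipped in the tests and the acceptance
script we chose smaller problem sizes once and kept them fixed: 64×64
frames, `tiny_widths()`, PPM bins (1, 2, 3, 4) (the deepest feature of a
64×64 input is 4×4, so bin 6 cannot fit), learning rate `1e-3` (appropriate
for the tiny batch regime), batch 8, at most 300 optimiser steps with an
optional early stop once a target foreground Dice is reached. The scaled
ablation benchmark uses 16 training and 8 test frames over 2 seeds and 60
steps per run; its baseline-versus-(PPM+AG) Dice ordering is logged rather
than asserted, because at this scale the comparison is stochastic. The
learning-sanity check trains 8 frames per seed and requires foreground
Dice ≥ 0.9 on them in at least 4 of 5 seeds.

## Numerical choices and degenerate inputs

* `0/0 = 1` uniformly for Jaccard/Dice/CPA ratios (absent classes score
  perfectly); aggregate means can exclude absent classes instead
  (`average = "present"`).
* Softmax is stabilised by per-pixel max subtraction; sort ties broken by
  pixel index; argmax ties resolve to the lower class index.
* BN uses `eps = 1e-5`, momentum 0.1, and running statistics at inference.
* Marching-tetrahedra surface extraction (6-tet cube split, edge-keyed
  vertex sharing, outward normals) runs on a Gaussian-smoothed
  (sigma = 1 voxel) zero-padded binary mask at iso-level 0.5; empty classes
  yield empty meshes with a warning. Uniform slice spacing is assumed — no
  probe-trajectory estimation.
* Label maps are only ever resampled nearest-neighbour; images bilinearly.
* The 9:1 train/test split is applied at sweep level by default to avoid
  adjacent-frame leakage (frame-level splitting is available).

## Known limitations

Double-precision CPU tensors only; no GPU path. The phantom benchmark
cannot reproduce clinical accuracy figures, and parameter counts of the
published full-width model depend on encoder widths that are not public.
The CLI's training subcommand operates on generated phantoms or manifests
of PNG frames; DICOM ingestion is out of scope.
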