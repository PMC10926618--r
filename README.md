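# sonoseg

Multi-target segmentation of transverse neck ultrasound frames — thyroid,
trachea, intra-thyroid nodules-or-vessels ("NoV"), esophagus, carotid artery
and background — with downstream 3-D visualization of scanned sweeps. The
package is aimed at researchers studying multi-organ ultrasound
segmentation pipelines who need a self-contained, fully testable
implementation: it ships its own speckled neck-phantom simulator, so every
stage runs end-to-end without clinical data.

## What is inside

* **Network** — a nested U-Net (U-Net++) grid `X[i,j]` with dense skip
  connections and deep supervision, augmented with a **pyramid pooling
  module** on the deepest encoder feature (average-pool to bins
  `(1, 2, 3, 6)`, 1×1-reduce to `C/N` channels, upsample, concatenate:
  channels exactly double) and **attention gates** on the decoder skip
  bundles (`Q = σ(BN(conv(ReLU(BN(conv(x)) + BN(conv(g)))))`, multiplied
  into the skip features). Runs on a package-internal reverse-mode autodiff
  engine with C++ kernels — no external deep-learning framework.
* **Loss** — the **Lovasz-Softmax loss**: for each class `c` the per-pixel
  error vector `E_i(c) = 1 − f_i(c)` on `{Y=c}` and `f_i(c)` elsewhere is
  sorted decreasingly and contracted with the prefix-difference gradient of
  the discrete Jaccard loss `Δ_Jc = 1 − |P_c∩G_c|/|P_c∪G_c|`; the result is
  the tight convex extension of `Δ_Jc`, averaged over classes.
* **Metrics** — confusion-matrix Dice `2TP/(2TP+FP+FN)`, IOU
  `TP/(TP+FP+FN)`, mIOU, pixel accuracy `trace/total`, per-class pixel
  accuracy `TP/(TP+FP)`, with the `0/0 = 1` convention for absent classes.
* **Phantoms** — seeded synthetic neck cross-sections (multiplicative
  mean-1 gamma speckle × piecewise-constant echogenicity, Gaussian PSF) and
  multi-frame sweeps cut from 3-D ellipsoids.
* **Preprocessing** — ROI crop / resize / rescale, non-local-means
  denoising, seeded paired augmentation (nearest-neighbour labels).
* **Trainer** — Adam, lr `1e-4` ×0.9 at epochs 100/150, batch 16,
  300 epochs by default; ablation grids over decode modes, PPM bins and
  module on/off combinations.
* **3-D reconstruction** — label-map stacking at uniform spacing, optional
  per-class morphological closing, marching-tetrahedra surface extraction,
  NIfTI / PLY / STL export with a colour-coded scene file.

## Worked example

Train a reduced-width model on 16 synthetic phantoms and evaluate on 8
held-out ones (a few minutes on one CPU core):

```r
library(sonoseg)

spec  <- phantom_spec(image_size = 64)
train_set <- phantom_dataset(16, spec, seed = 1)
test_set  <- phantom_dataset(8,  spec, seed = 10001)

mcfg <- model_config(encoder_widths = tiny_widths(), ppm_bins = c(1, 2, 3, 4))
tcfg <- train_config(lr = 1e-3, batch_size = 8, epochs = 150,
                     image_size = 64, val_fraction = 0, seed = 1)
fit <- train(mcfg, tcfg, train_set, stop_fg_dice = 0.93, stop_check_every = 20)

evaluate(fit$model, test_set)
```

Output printed by the final call (seed 1):

```
Segmentation metrics (class average: all )
mean Dice 0.8747 | mIOU 0.7923 | PA 0.9644
```

meaning: averaged over all six classes the Dice overlap between predicted
and true masks is 0.87, mean intersection-over-union 0.79, and 96.4% of all
pixels are labelled correctly — on speckled frames the model never saw.
Reconstruct and mesh a sweep:

```r
sw  <- sweep_spec(n_frames = 64, slice_spacing = 1, image_size = 64)
out <- generate_sweep(sw, spec, seed = 1)
vol <- stack_predictions(out$label_frames, spacing = 1)
mesh <- extract_mesh(vol, class_index = 1)     # thyroid surface
export_recon(vol, list(mesh), "recon_out")     # NIfTI + PLY/STL + scene.json
```

A command-line wrapper with `synth`, `train`, `eval`, `predict`, `ablate`
and `reconstruct` subcommands is installed at
`system.file("cli", "sonoseg.R", package = "sonoseg")`.

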