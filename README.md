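# epanet

Semantic segmentation of field imagery into **background / bean seedling /
weed** with EPAnet: an ERFnet-style encoder–decoder extended with
parameter-free SimAM attention, a DO-Conv feature-pyramid connector
(FDPN), a point-wise spatial attention (PSA) decoder head, and a coupled
cross-entropy + Dice loss. The package is aimed at agricultural
image-analysis work — distinguishing crop seedlings from weeds for
precision weeding — and at anyone who wants a fully inspectable,
pure-R/C++ implementation of these mechanisms with tests against
independent oracles.

## The model in brief

* **Backbone**: 24 layers. Encoder L1–L16: three stages, each opened by a
  concat downsampler (stride-2 3×3 conv ∥ 2×2 max-pool) followed by SimAM,
  with Non-bottleneck-1D residual blocks (factorized 3×1/1×3 convolutions,
  dilations 2,4,8,16 ×2 in stage 3) at widths 16/64/128. Decoder L17–L24:
  transposed-conv upsamplers and Non-bt-1D blocks, the PSA head at L23,
  and a final transposed convolution to class logits.
* **SimAM** weights every activation by `sigmoid(1/e*)`, where
  `e* = 4(σ²+λ) / ((t−μ)² + 2σ² + 2λ)` is the closed-form minimum of a
  per-neuron linear-separability energy (channel mean μ, variance σ²,
  regularizer λ = 1e-4). No trainable parameters.
* **FDPN** fuses encoder taps (strides 2/4/8) through 1×1 DO-Conv
  laterals, top-down 2× upsample-and-add, and 3×3 DO-Conv smoothing, and
  injects the fused maps additively into the decoder at strides 4 and 2.
  A DO-Conv trains a depthwise operator composed with a conventional
  kernel; the composition always equals one convolution with the folded
  kernel.
* **PSA head**: each position predicts a `(2H−1)(2W−1)`-channel
  over-complete vector whose centred H×W crop is its attention map;
  symmetric Collect/Distribute branches aggregate
  `z_i = (1/HW) Σ_j a_ij x_j` and its transpose.
* **Loss**: `0.6·CE + 0.4·(1 − Dice)` on softmax probabilities.
* **Metrics**: per-class precision/recall/F1/IoU plus overall accuracy,
  mIoU and frequency-weighted IoU, all from one confusion matrix.

Everything runs on a small reverse-mode autodiff engine with C++
(im2col + GEMM) convolution kernels — no external deep-learning
framework — so the whole computation graph is testable down to numeric
gradient checks.

## Worked example

Train the full model on eight deterministic synthetic crop/weed scenes
(64×64, textured soil, elliptical seedling leaves, thin weed strokes)
and evaluate it on the same scenes — the standard mechanism check that
the network, losses and metrics cooperate:

```r
library(epanet)

pairs <- render_scenes(8, scene_spec(seed = 7))
fit <- epanet_train(pairs,
                    cfg = train_config(lr = 0.0025, batch_size = 8,
                                       max_iters = 200, epochs = 200,
                                       optimizer = "adam", poly_power = 0,
                                       eval_every = 10, stop_miou = 0.95,
                                       seed = 1))
cat("stopped after", max(fit$history$iter), "iterations; train mIoU",
    round(100 * fit$best_miou, 2), "\n")
print(epanet_evaluate(fit$net, pairs))
```

```
stopped after 60 iterations; train mIoU 95.23
method  precision_background  recall_background  f1_background  precision_bean_seedling  recall_bean_seedling  f1_bean_seedling  precision_weed  recall_weed  f1_weed  overall_accuracy  iou_background  iou_bean_seedling  iou_weed  miou   fwiou
model   99.75                 99.20              99.47          98.70                    99.09                 98.89             91.09           97.39        94.14    99.09             98.95           97.81              88.92     95.23  98.23
```

Reading the table: the soil background and the broad-leaved seedlings are
segmented almost perfectly (IoU 98.95 and 97.81); the thin weed strokes
are the hard class (IoU 88.92) because a one-pixel halo on a 2–4 px
stroke costs a large fraction of its area — exactly the small-object
regime the PSA head and FDPN skips are there to help with. mIoU averages
the three classes equally; FWIoU weights them by pixel frequency, so it
sits near the background's IoU.

The SimAM energy is available directly; for the channel `[0, 0, 2, 2]`
every neuron is one unit from the mean, so all energies agree:

```r
simam_energy(array(c(0, 0, 2, 2), dim = c(1, 4, 1, 1)))
#> 1.454575 1.454575 1.454575 1.454575   # = 4(4/3+λ)/(1+8/3+2λ)
```

Real datasets use the public layout (one folder per sample with
`false.png` + `gt.png`): `load_dataset()`, `split_dataset()` (7:2:1,
seeded) and `expand_offline()` (nine offline augmentations, training
split only) take it from there. A thin command-line driver is shipped at
`inst/cli/epanet.R`:

```sh
Rscript inst/cli/epanet.R synth --n 8 --size 64 --seed 7 --out fixtures/
Rscript inst/cli/epanet.R train --data fixtures/ --preset epanet-full --out run/
Rscript inst/cli/epanet.R eval  --checkpoint run/checkpoint.rds --data fixtures/ --report run/report.csv
Rscript inst/cli/epanet.R predict --checkpoint run/checkpoint.rds --image fixtures/scene_001/false.png --out mask.png
```

The five incremental ablation configurations (ERFnet baseline → +PSA →
+coupled loss → +SimAM → +FDPN) ship as YAML presets under
`inst/configs/`.

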