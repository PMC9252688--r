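# busseg

Lesion segmentation for 2-D grayscale breast ultrasound images with a
residual attention U-Net, in pure R.

Breast ultrasound is a first-line imaging modality for breast masses,
but its images carry heavy multiplicative speckle, low lesion/tissue
contrast and smooth intensity nonuniformity, which defeats simple
thresholding and makes automatic delineation hard.  `busseg` provides
the full pipeline for this problem — preprocessing, network, training,
evaluation — plus an ultrasound phantom simulator with exact ground
truth, so everything runs and is verified on a single CPU without any
clinical data.  It is aimed at method developers and students who want
an inspectable, fully tested reference implementation rather than a
black-box framework.

## The method

* **Network** — a U-Net whose level blocks are residual units
  `u = c(v, w_h) + w v` (two conv + batch-norm + ReLU layers plus a 1×1
  projection for dimension matching), with each skip connection gated
  by a spatial–channel attention block (SCAB): a spatial gate from
  channel-pooled mean/max maps (k×k conv + sigmoid) and a channel gate
  from globally pooled descriptors through a shared bottleneck, fused
  by concatenation and a 1×1 projection, `d = proj(Cat(e_s, e_c))`.  A
  residual attention variant (RSCAB) is also available.  Forward and
  backward passes are hand-implemented in vectorized R with a small
  compiled im2col kernel; analytic gradients are verified against
  finite differences.
* **Loss** — `loss_NEW = τ·loss_BCE + loss_DICE` with τ = 1.5e-3: the
  soft-Dice term handles foreground/background imbalance, the small
  cross-entropy term keeps per-pixel gradients informative.
* **Training** — He-scaled Gaussian initialization (sd = √(2/δ),
  δ = k²·fan-in) and Adam (φ₁ = 0.95, φ₂ = 0.999, σ = 1.5e-8), fully
  seeded and bit-reproducible.
* **Evaluation** — Dice, IoU, Hausdorff distance and mean absolute
  boundary deviation, with a brute-force-verified boundary-distance
  core.
* **Phantoms** — perturbed-ellipse lesions (exactly known masks),
  hypoechoic contrast, multiplicative Gaussian speckle and a smooth
  polynomial bias field.

See `vignettes/busseg-methods.Rmd` for the model, its assumptions,
parameter defaults and limitations.

## Worked example

```r
library(busseg)

# 200 training + 50 validation phantoms: 64x64, low contrast (0.15),
# heavy speckle (sigma 0.3), smooth bias field
cfg   <- phantom_config()
train <- generate_dataset(cfg, 200, seed = 101)
val   <- generate_dataset(cfg, 50,  seed = 202)

model <- build_model(arch_config(depth = 3, base_channels = 8), seed = 1)
res <- fit(model, train, val, loss = "composite",
           adam_cfg = train_config(), epochs = 10, seed = 1,
           verbose = TRUE)
#> epoch 1  train composite = 0.08173  val Dice = 0.5152
#> epoch 2  train composite = 0.02476  val Dice = 0.9643
#> ...
#> epoch 10  train composite = 0.01482  val Dice = 0.9762

test <- generate_dataset(cfg, 50, seed = 303)
pred <- predict(res$model, lapply(test, `[[`, "image"), type = "mask")
evaluate_set(pred, lapply(test, `[[`, "mask"))
#> <metrics_report> over 50 image(s)
#>   Dice 0.9770  IoU 0.9550  HD 2.264 px  MAD 0.461 px
```

The history shows the composite loss falling while held-out Dice rises
from near-chance to ~0.98 within a few epochs; on unseen phantoms the
model overlaps the true lesion at Dice ≈ 0.98 with boundary errors of
about half a pixel on average (MAD) and ~2 px worst-case (HD).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/busseg.R simulate --out data --n 100 --seed 1
Rscript inst/cli/busseg.R train --data data --out run --seed 1
Rscript inst/cli/busseg.R predict --model run/checkpoint.rds --in data --out pred
Rscript inst/cli/busseg.R evaluate --pred pred --truth data --out report.tsv
```

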