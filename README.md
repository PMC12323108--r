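# pancseg

Pancreas segmentation and fat quantification from abdominal CT in R.

Accurate delineation of the pancreas on CT is the prerequisite for measuring
pancreatic steatosis — ectopic fat accumulation linked to type 2 diabetes and
metabolic syndrome. The organ is small, irregular, and surrounded by tissue
of similar attenuation, so plain convolutional U-Nets, which see only local
receptive fields, struggle with it. `pancseg` implements a **dual
self-attentive transformer U-Net** for this task together with the
downstream **fat-volume-fraction (FVF)** estimator, plus everything needed
to exercise the pipeline end to end on synthetic CT phantoms: deterministic
preprocessing, a Hungarian-matched mask-classification training objective,
surface-distance metrics, and a seeded phantom generator.

## The model

The network wraps a transformer between a CNN encoder and decoder:

- **CNN encoder** — feature pyramid at strides 1/2/4/8; the deepest map
  feeds the transformer, the others serve as skip connections.
- **Transformer encoder** — a stack of *dual self-attention layers*
  (DuSALs). Each layer applies, with pre-norm residual connections,
  (i) windowed spatial self-attention
  `softmax(Q K^T / sqrt(d) + P) V` within non-overlapping `n x n` windows
  (`P` a learnable relative positional bias), (ii) spectral self-attention:
  the map is taken to the frequency domain (FFT, or Haar DWT), and
  channel–channel attention `softmax(sigma K^T Q) V` mixes frequency
  channels, and (iii) a two-layer MLP. The block ends with a 3x3
  convolution and a long residual from the block input.
- **Mask-classification decoder** — `X` learned *organ queries* predict a
  coarse mask by dot product with the decoder features, binarized at
  `tau = 0.6`. *Granular attention refinement* then iterates: each query
  attends only to pixels inside its current mask (attention logits are
  `-Inf` elsewhere — masked cross-attention), updates residually, and
  re-predicts its mask. A linear head assigns each refined query a class
  (pancreas / background / no-object).

Training minimizes the Hungarian-matched set-prediction loss

```
L = alpha * (L_ce + L_dice) + beta * L_clas,   alpha = 0.7, beta = 0.3
```

where predicted masks are matched to ground-truth instances by a
minimum-cost bipartite assignment.

Downstream, pancreatic volume is `PV = M * (U * V * W)` (voxel count times
voxel volume, in ml) and fat voxels are those at or below **-20 HU** inside
the mask; `FVF% = 100 * fat voxels / M`.

Because no deep-learning framework exists in this R stack, the network runs
on a small reverse-mode autodiff tape written for this package
(`R/autodiff.R`); every gradient is verified against finite differences and
every attention mechanism against explicit-loop oracles in the test suite.

## Worked example

```r
library(pancseg)

# a 24 x 64 x 64 CT phantom (3 x 1 x 1 mm voxels) with 20% injected fat
ph <- make_phantom(phantom_spec(fat_fraction = 0.20, seed = 5))
ph$truth$volume_ml
#> [1] 15.132

# fat quantification with the ground-truth mask
fat_volume_fraction(ph$ct, ph$mask)
#> <quant_report> PV 15.13 ml | fat 3.02 ml | FVF 19.98% | 1008/5044 voxels <= -20 HU
```

The report says the phantom's pancreas occupies 15.13 ml, of which 3.02 ml
(19.98%) lies at or below -20 HU — within 0.02 percentage points of the
injected 20% fat fraction.

Training and inference at desk scale:

```r
data  <- make_toy2d_dataset(8, size = 32, seed = 3)   # 8 blob slices
cfg   <- model_config(base_channels = 16, n_dusal = 2, window = 4,
                      heads = 4, t_refine = 2)
model <- init_model(cfg, seed = 1)
model <- train_model(model, data, epochs = 200, lr = 1e-3)
glance(model)
#> # A tibble: 1 x 4
#>   n_params epochs final_loss final_train_dice
#>      <dbl>  <int>      <dbl>            <dbl>
#> 1  1066301     50     0.0206            0.997

held <- make_toy2d_dataset(2, size = 32, seed = 99)[[1]]
r <- segment_slice(model, condition_slice(held$image, model$norm))
dice(r$label, held$mask)
#> [1] 94.52055
```

Volumes go through `predict_volume()` (sliding-window inference with
Gaussian-weighted fusion) and `evaluate_segmentation()` /
`quantify_case()` for metrics and FVF reports. A command-line wrapper with
`simulate`, `preprocess`, `train`, `predict`, `evaluate` and `quantify`
subcommands is installed at `inst/cli/pancseg`.

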