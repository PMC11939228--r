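# ghostgan

Mask-conditioned generative adversarial networks with ghost-module
encoders, for augmenting paired medical-imaging datasets — implemented as
a self-contained R package with its own C++ (RcppArmadillo) convolution
and backpropagation kernels, so the entire pipeline trains and evaluates
on a single CPU with no deep-learning framework.

## What it does, and for whom

Segmentation and classification models in medical imaging are limited by
small, imbalanced labeled datasets. A conditional GAN can augment them:
given a **binary lesion mask**, the generator synthesizes a plausible scan
whose lesion sits exactly where the mask says, so every generated image
comes with free, exact ground truth. This package is for researchers who
want a tested, reproducible, CPU-scale implementation of that idea —
including the two components that make it cheap and sharp:

- **Ghost-module encoder.** Each downsampling block computes only
  `m = C_out/s` *intrinsic* feature maps with a dense convolution and
  derives the remaining maps with cheap depthwise convolutions,
  concatenating `[intrinsic, ghost]`. Parameter cost falls from
  `C_in C_out k²` to `m C_in k_p² + m (s−1) k_c²` — a factor ≈ `s`
  (default 2). Toggling `use_ghost_encoder` reproduces the ablation
  between ghost and dense encoders at identical widths.
- **Hybrid objective.** The generator minimizes
  `L = w_bce · L_BCE + w_ssim · (1 − SSIM(y, ŷ))`
  — adversarial binary cross-entropy on a conditional patch
  discriminator's logits plus a structural-similarity loss (Gaussian
  11×11 window, σ = 1.5, K₁ = 0.01, K₂ = 0.03), with an analytic SSIM
  gradient for backpropagation. MSE and pixel-BCE arms are included for
  loss-comparison studies.

Because real paired scan/mask data cannot ship with code, the package
generates **tumor phantoms** — ellipse-union masks over smooth
backgrounds with elevated lesion intensity and Gaussian noise — that
structurally emulate paired 2D brain-tumor segmentation data (grayscale
scan + binary mask, 256×256 by default). Everything downstream
(preprocessing 256→286→random-crop-256, [−1,1] normalization,
0.8/0.1/0.1 seeded splits, adversarial training, SSIM evaluation,
parameter-cost accounting) runs on phantoms deterministically from a
single seed.

## Worked example

```r
library(ghostgan)

# 32 paired phantoms at 64 px, deterministic from the spec seed
spec <- phantom_spec(image_size = 64, tumor_radius_range = c(4, 12), seed = 11)
man  <- make_phantom_dataset(32, spec, "phantoms64")

# CPU profile: 64 px, batch 8, base width 16, 200 steps
cfg <- desk_profile(seed = 1, steps = 200)
run <- train_gan(man, cfg)

head(run$history$l_combined, 3)   # 1.7340 1.6748 1.6292
mean(head(run$history$l_combined, 10))  # 1.526
mean(tail(run$history$l_combined, 10))  # 1.193  — falling combined loss

# held-out phantoms: trained vs freshly initialized generator
held <- make_phantom_dataset(8, phantom_spec(image_size = 64,
        tumor_radius_range = c(4, 12), seed = 211), "held64")
evaluate_ssim(run$gen, held, split = "all", seed = 50)$mean_ssim   # 0.5286
set.seed(99)
fresh <- build_generator(run$gen$spec)
evaluate_ssim(fresh, held, split = "all", seed = 50)$mean_ssim     # 0.3391

# ghost-module cost accounting (closed forms, verified against allocation)
ghost_param_count(ghost_config(16, 32, ratio = 2))   # 2448
standard_conv_param_count(16, 32, 3)                 # 4608
model_cost(run$gen$spec)$generator_params_ghost      # 195505
model_cost(run$gen$spec)$generator_params_standard   # 242881
```

The SSIM numbers say the 200-step smoke-trained generator reconstructs
held-out phantom scans substantially better than chance initialization;
the parameter counts show the ghost encoder saving ~20% of the generator
at these widths (the saving grows with width since it applies to every
dense encoder convolution).

A thin command-line front end is installed at
`system.file("cli", "ghostgan.R", package = "ghostgan")` with
`make-phantoms`, `split`, `train` (`--no-ghost`, `--loss bce|mse|combined`),
`evaluate`, `generate`, and `cost` subcommands.

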