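---
title: "Mask-conditioned image synthesis with ghost-module encoders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-conditioned image synthesis with ghost-module encoders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostgan)
```

## The problem

Deep models for tumor segmentation and classification are starved for
labeled medical images. One remedy is conditional generative
augmentation: train a generator that maps a *binary lesion mask* to a
plausible scan image, so new training pairs can be synthesized with
exact, free ground-truth annotations — the mask itself dictates where the
lesion appears. `ghostgan` implements such a mask-conditioned GAN as a
pure-R/C++ library: a U-Net-style generator whose encoder uses *ghost
modules* for cheap feature expansion, a conditional patch discriminator,
and a hybrid training objective combining adversarial binary
cross-entropy with a structural-similarity (SSIM) term.

The conditional GAN maps an observed conditioning image and a noise
source to an output image. Here the conditioning image is the mask, the
noise enters through decoder dropout that stays active at generation
time (the standard convention for conditional translation models, where
an explicit noise vector tends to be ignored by the generator), and the
output is a synthetic scan in the same pixel grid.

## The ghost module

A dense convolution mapping $C_{in}$ to $C_{out}$ channels with a
$k \times k$ kernel costs $C_{in} C_{out} k^2$ parameters. The ghost
module observes that many learned feature maps are inexpensive variations
of others, and therefore:

1. computes only $m = C_{out}/s$ *intrinsic* maps with a dense "primary"
   convolution ($m C_{in} k_p^2$ parameters),
2. derives $s - 1$ *ghost* maps from each intrinsic map with a cheap
   depthwise convolution ($m (s - 1) k_c^2$ parameters),
3. passes the intrinsic maps through unchanged (identity mapping) and
   concatenates `[intrinsic, ghost]` to restore $C_{out}$ channels.

The ratio of parameter costs is therefore roughly $s$ for realistic
channel counts. The package exposes the closed forms
(`ghost_param_count()`, `standard_conv_param_count()`,
`compression_report()`) and the tests verify that the counted numbers
equal the scalars actually allocated by `init_ghost_params()`:

```{r}
cfg <- ghost_config(16, 32, ratio = 2)
c(ghost = ghost_param_count(cfg), standard = standard_conv_param_count(16, 32, 3))
compression_report(cfg)$compression_ratio
```

Design choices the literature leaves open, fixed here once:

* the cheap operation is a depthwise $3 \times 3$ convolution (the
  canonical ghost-network choice among the "linear operations" admitted
  by the idea);
* the default ratio is $s = 2$, the canonical setting; it is a
  configuration field, not a constant;
* the identity mapping is realized as concatenation of the unchanged
  intrinsic maps, not as a residual addition;
* `ghost_forward()` itself is purely convolutional; batch normalization
  and the nonlinearity are applied by the enclosing encoder stage, which
  keeps the block's algebraic contract (e.g. a centred delta cheap kernel
  makes ghost maps equal their sources exactly) testable.

## Networks

**Generator.** `depth` stride-2 encoder stages (ghost blocks, or dense
convolutions under the ablation toggle `use_ghost_encoder = FALSE`),
widths doubling from `base_width` and capped at eight times it; a
mirrored decoder of nearest-neighbour upsampling + convolution stages,
each concatenating the skip tensor from its mirror encoder stage; a
final convolution and `tanh`, so outputs live in $[-1, 1]$ exactly like
the normalized inputs. Batch normalization everywhere except the first
encoder stage; LeakyReLU(0.2) in the encoder, ReLU in the decoder;
dropout (rate 0.5) on the up-to-three deepest decoder stages. For small
inputs the depth auto-reduces to $\log_2(\text{size}) - 2$, keeping a
$4 \times 4$ bottleneck.

**Discriminator.** A conditional patch discriminator: mask and scan are
concatenated channel-wise; `n_layers` stride-2 $4 \times 4$ convolution
stages are followed by one stride-1 stage and a 1-channel stride-1
output convolution. Each output logit judges one local patch of the
pair; at $256 \times 256$ with three stride-2 stages the output is a
$30 \times 30$ grid with a $70 \times 70$ receptive field per logit (both
are asserted in the tests). Sigmoid is applied only inside the loss, so
logits remain unbounded and the loss can be computed stably in logit
space.

The upsampling path uses nearest-neighbour resize followed by a
$3 \times 3$ convolution rather than transposed convolution; this avoids
checkerboard artifacts and keeps the adjoint (backward) operator simple.

## The objective

With discriminator patch logits $z$ on generated pairs, generator output
$\hat y$ and ground truth $y$:

$$ L_{\mathrm{BCE}} = -\tfrac1N \sum_i \big[ t_i \log \sigma(z_i) + (1 - t_i)\log(1 - \sigma(z_i)) \big], \qquad
   L_{\mathrm{SSIM}} = 1 - \mathrm{SSIM}(y, \hat y), $$

$$ L_{\mathrm{combined}} = w_{\mathrm{bce}} L_{\mathrm{BCE}} + w_{\mathrm{ssim}} L_{\mathrm{SSIM}}, $$

with both weights defaulting to 1 (the combination as printed; the
weights exist because a weighted combination is explicitly
contemplated). The discriminator minimizes the symmetric BCE of real
pairs against 1 and fake pairs against 0, halved.

Whether the BCE term of the generator objective runs over pixels or over
discriminator judgments is genuinely ambiguous in the source
formulation; this package defaults to the **adversarial reading**
(`bce_target = "adversarial"`): BCE of the discriminator's patch logits
on generated pairs against the "real" target, which is the standard
generator loss in conditional adversarial training, with SSIM supplying
the image-space term. The pixel-wise reading (BCE between
$[0,1]$-rescaled generated and real images) is implemented behind
`bce_target = "pixel"` so both interpretations can be compared. A
mean-squared-error arm (`loss_mode = "mse"`) completes the three-way
loss comparison (adversarial BCE alone, + MSE, + SSIM).

### SSIM: constants, window, gradient

SSIM follows the canonical formulation: an $11 \times 11$ Gaussian
window with $\sigma = 1.5$, constants $C_1 = (K_1 L)^2$,
$C_2 = (K_2 L)^2$ with $K_1 = 0.01$, $K_2 = 0.03$, population (windowed,
uncentred) covariances, and the map averaged over all fully interior
window positions ("valid" filtering — equivalent to the common
reference implementation, against which the tests check agreement to
$10^{-6}$ on random images). $L$ is the dynamic range: **2** for
$[-1,1]$ training tensors, **255** for 8-bit evaluation images. The
training loss and the evaluation metric therefore use the same code with
different $L$; both conventions are reported explicitly wherever scores
appear.

Because every local SSIM statistic is a Gaussian-filtered function of
the pixels, the loss gradient needed for generator training has a closed
form: differentiate the SSIM map with respect to the windowed means and
covariances and scatter the result back through the (self-adjoint)
Gaussian filter. The implementation is verified against central
differences in the test suite.

## Synthetic tumor phantoms

Real paired datasets (scan + lesion mask) cannot ship with a package, so
`ghostgan` generates *phantoms*: the mask is a union of 1–2 random
ellipses (semi-axes 8–40 px at 256 px, scaled proportionally for smaller
images; orientation uniform), and the scan is a smooth background — a
concentric gradient from 120 at the centre to 40 at the corners, or a
low-frequency random field on the same range — with the masked region
set to intensity 220 plus Gaussian pixel noise ($\sigma = 8$) and
clipping to $[0, 255]$. Each pair is a pure function of
`(seed, index)` (the per-pair stream is seeded with `seed + index`), so
datasets are bit-reproducible and order-insensitive.

Ellipses on a smooth background are deliberately the *simplest* geometry
that preserves the property the conditional model must learn — the mask
determines where the lesion appears and the lesion is locally brighter
than its surround. What phantoms do **not** emulate: anatomical texture,
partial-volume edges, intensity inhomogeneity across scanners, or any
multi-class lesion structure. Passing tests on phantoms therefore
demonstrate that the architecture, losses, gradients and training loop
are correct and that conditioning is learned — not that the model
produces clinically realistic images; that claim would need the real
benchmark data at full training scale.

Masks are treated as strictly binary throughout (re-thresholded at 127
after any interpolation); multi-label conditioning is out of scope.

## Preprocessing

The pipeline mirrors the standard conditional-translation recipe:
resize pairs to $286 \times 286$ (bilinear for scans, nearest-neighbour
+ threshold for masks, preserving binarity), randomly crop back to
$256 \times 256$ with a *single* offset applied to mask and scan jointly
(joint cropping is forced by paired training), and scale intensities to
$[-1, 1]$ via $x / 127.5 - 1$. Crops are resampled fresh every epoch at
training time; evaluation uses the deterministic $(0,0)$ crop. Splitting
is 0.8/0.1/0.1 by a seeded permutation with floored train and validation
counts and the remainder going to test — one documented, tested rule (at
$n = 3064$: 2451/306/307). Coordinates are row-major, origin top-left,
0-based, half-open windows; `denormalize_image()` uses round-half-up.

## Training

Alternating optimization, one discriminator step then one generator
step per batch, both with Adam ($\beta_1 = 0.5$, $\beta_2 = 0.999$ — the
first-moment reading of the optimizer description, with $\beta_2$ at the
framework default; no learning-rate schedule). Reference-scale defaults
are batch 64, learning rate $10^{-3}$, 400 epochs at 256 px; that
profile is GPU-scale and is not exercised by the tests.

Two profiles ship:

| profile | size | batch | base width | D layers | steps |
|---|---|---|---|---|---|
| `train_config()` (reference) | 256 | 64 | 64 | 3 | 400 epochs |
| `desk_profile()` (CPU) | 64 | 8 | 16 | 2 | 200 |

**Adversary balance.** In short CPU runs an equally-fast discriminator
wins quickly: its loss collapses while the generator's adversarial term
inflates, masking real progress in the reconstruction term. The trainer
therefore uses two-time-scale updates — the discriminator's learning
rate is `disc_lr_factor` (default 0.1) times the generator's — chosen so
the discriminator loss hovers near its $\ln 2$ equilibrium at desk scale
instead of collapsing. The factor is a configuration field; setting it
to 1 restores symmetric updates.

Determinism: the run seed is the only entropy source (initialization,
shuffling, crops, dropout all draw from the single R RNG stream), all
C++ kernels are single-threaded, and checkpoints store the RNG state,
optimizer state, epoch permutation and position, so a resumed run
reproduces the uninterrupted run's loss records exactly. Non-finite
losses abort training with the step and term named.

The test suite's smoke conditions — 32 phantom pairs at 64 px, batch 8,
200 steps, three seeds — were sized so the whole suite runs in minutes
on one CPU while still showing falling combined loss and a trained
generator beating an untrained one on held-out phantoms.

## Evaluation and cost accounting

`evaluate_ssim()` regenerates a scan from every mask of a split and
scores SSIM against the ground-truth scan on denormalized 8-bit images
($L = 255$), reporting per-image scores and their mean; writing PNGs and
re-reading them changes nothing because the 8-bit round trip is exact.
`model_cost()` reports parameter counts for the ghost and dense encoder
variants at identical widths and a parameter-memory estimate at 4 bytes
per float32 parameter — a reproducible, hardware-free convention
(activation memory, which depends on batch and resolution, is not
included). The ablation toggle changes only the encoder, so decoder and
discriminator costs are invariant across it, which the tests assert.

## Known limitations

* Phantom realism, as discussed above: correctness and controllability
  are demonstrated, clinical image quality is not.
* The reference-scale profile (256 px, 400 epochs) is provided but
  untested here; CPU wall-clock at that scale is impractical.
* Batch normalization uses running statistics at evaluation; very small
  generation batches therefore depend on training-time statistics.
* Single-channel (grayscale) pipelines are the default; multi-channel
  inputs are supported by the tensor layout but not exercised end to
  end.
* The discriminator architecture is the field-standard patch design; the
  source formulation specifies only its role, so no claim is made that
  it matches the original layer-for-layer.
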