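---
title: "Dual-diffusion pressure-map restoration and 3D posture estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-diffusion pressure-map restoration and 3D posture estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactpose)
```

## The problem

A pressure-sensitive floor mat reports, at 60 Hz, a 2D grid of normal
pressures (kPa) produced by a person standing, squatting, planking or
otherwise touching it. The sensing surface targeted here is a 1.80 m x
0.60 m capacitive array (45 x 16 tactels, resampled to 496 x 298 frames)
that resolves pressures up to a 15 kPa ceiling with 0.1 kPa sensitivity.
From a single such frame we want the 3D positions (mm) of 12 body keypoints
— head, shoulders, elbows, hands, pelvis, knees, feet — as recorded by a
marker-based motion-capture system during training.

Two obstacles make this hard: the frames are *sparse* (only contact areas
carry signal) and *noisy* (sensor noise plus spurious small blobs that look
deceptively like real contacts). `tactpose` therefore works in two stages:

1. **Stage 1 — dual-diffusion signal enhancement.** The frame is restored by
   a denoising diffusion model whose reverse process is conditioned, at
   every step, on a morphologically refined foreground mask diffused in
   parallel with the signal.
2. **Stage 2 — pose regression.** The restored frame is mapped to the 12
   keypoints by a transformer encoder, a deconvolutional decoder, and a
   linear keypoint head.

## Stage 1 model

### Forward diffusion of signal and mask

Both streams share one noise schedule. With per-step retention factors
$\alpha_t$ decaying linearly from `alpha_start` (t = 1) to `alpha_end`
(t = D), a forward step in the default variance-preserving parameterisation
is

$$x_t = \sqrt{\alpha_t}\, x_{t-1} + \sqrt{1 - \alpha_t}\, \epsilon_t,
  \qquad \epsilon_t \sim \mathcal N(0, I),$$

applied independently (separate $\epsilon$ draws, same schedule) to the
normalised pressure frame and to the refined binary mask, which thereby
becomes a *soft* mask for every $\alpha_t < 1$. A `linear_retention` mode
without the square root on the retention factor is kept behind the
`mode` switch of `make_schedule()`: descriptions of this recursion are
sometimes written without the square root, and the variance-preserving
form is the standard one in the diffusion literature, so it is the
default while the alternative reading remains available for comparison.
Closed-form marginals (`diffusion_signal_scale()`,
`diffusion_marginal_var()`) are obtained by unrolling the recursion; they
drive both the efficient per-step training pairs and the Monte-Carlo
validation tests.

The schedule length and endpoints are tunables with no single published
value; the package defaults are $D = 50$, $\alpha$ from 0.999 to 0.95.
Desk-scale runs in the tests and the acceptance script use $D = 10$ with
$\alpha$ from 0.99995 to 0.9999, so a full reverse chain costs ten network
evaluations. The endpoints matter more than they look: the reverse chain
here is deterministic and seeded only by the forward-diffused observation,
so information destroyed by the forward pass is never recovered —
restoration quality degrades monotonically with the total injected
variance. Production-length diffusion schedules use per-step retention
factors of the same order ($1 - \alpha_t \approx 10^{-4}$); a short desk
chain keeps the per-step increments, not the accumulated total, which
leaves the total diffusion noise commensurate with the sensor noise the
model is asked to remove.

### Refined mask

The mask is produced from the raw input frame (step $t = 0$) by
thresholding followed by a morphological opening: `n_erosions = 3` binary
erosions then `n_dilations = 3` dilations with a solid 5 x 5 square, at the
sensor's native resolution. Opening with this operator removes every
foreground component that cannot contain a 13 x 13 square while leaving
large contact areas essentially intact; the synthetic generator's spurious
blobs are strictly smaller than the kernel, so their removal is provable
rather than statistical. The threshold default is Otsu's method computed on
the frame's nonzero pixels (an absolute threshold in kPa can
be set instead); outside-frame pixels count as background, which shrinks
foreground conservatively at the border. At down-scaled desk resolutions
(32 x 20 frames) the same opening would erase genuine foot contacts, so
desk-scale runs scale the operator down with the resolution
(3 x 3 kernel, one erosion/dilation) — the structuring element should span
roughly the same physical extent, not the same pixel count.

### CDA: fusing mask contours into the signal stream

At the entrance of the denoising U-Net, the contour detection and alignment
layer lifts each stream through a 1 x 1 stem (plus a learned projection of
the sinusoidal step embedding, added to both stems), then

* **pyramidal pooling (PP):** four parallel 3 x 3 atrous convolutions at
  rates 2, 4, 6, 8 ("same" padding) over the mask stream, concatenated and
  projected back to the stream width — a multi-scale contour descriptor;
* **spatially pooled cross-attention (CA):** multi-head scaled dot-product
  attention whose queries come from the pressure stream pixels and whose
  keys/values come from the PP output after non-overlapping average pooling
  (default 4 x 4), residual-added to the pressure stream.

The direction of fusion (mask into pressure) follows from the layer's
purpose: contour features guide where the signal should be trusted.
Attention output is residual-added rather than replacing the stream, and
the CDA is re-applied at every reverse step so the conditioning tracks the
current noise level. Both choices were genuinely open; the residual form
keeps the layer a strict refinement (zero-weight attention reduces to the
plain U-Net), and per-step reapplication matches the step-indexed inputs
the layer receives.

### U-Net and reverse denoising

The U-Net is a standard symmetric encoder-decoder with skip connections:
per level a 3 x 3 convolution + ReLU and 2 x 2 mean-pool down, a 3 x 3
bottleneck, then per level a 2 x 2 stride-2 transposed convolution, skip
concatenation and a 3 x 3 convolution + ReLU, with a 1 x 1 head back to one
channel. Inputs whose sides are not divisible by $2^{\text{depth}}$ are
zero-padded symmetrically and cropped after. The network predicts a
*residual correction* that is added to its pressure input: the identity map
is then the starting point of training, which matters at desk scale where
training budgets are tiny.

Restoration of a frame runs: refine the mask from the raw input;
forward-diffuse frame and mask to step $D$, storing both trajectories;
then iterate $\hat P_{t-1} = U_\theta(\mathrm{CDA}(\hat P_t, M_t, t))$
from $t = D$ down to 1, conditioning each step on the *stored* diffused
mask (the two trajectories are synchronized by construction), and clip the
result to $[0, 15]$ kPa. The chain starts from the forward-diffused
observation, not from pure noise: the model restores a specific input.

### Stage-1 training

Training pairs are per-step along the noisy-to-clean path. For a random
step $t$ the input is the forward diffusion, to step $t$, of the
interpolant $P_{\text{clean}} + \tfrac{t}{D}(P_{\text{noisy}} -
P_{\text{clean}})$, conditioned on the independently diffused refined
mask; the MSE target is the signal-scale-$(t-1)$ multiple of the
interpolant at $\tfrac{t-1}{D}$. Two properties follow. First, the
training inputs match the reverse chain's own intermediates at *every*
step, not just at $t = D$ — a design trained only on diffusions of the
noisy frame leaves the chain's own iterates off-distribution, so its
prediction errors accumulate instead of cancelling. Second, each reverse step
removes exactly $1/D$ of the sensor noise plus that step's diffusion
noise, so the composition of $D$ steps lands on the clean frame without
over-applying the denoiser. Clean frames exist because the synthetic
renderer provides them; on real recordings any user-supplied clean
reference fills the same role.

Two further choices proved load-bearing at desk scale. The U-Net predicts
a residual correction added to its pressure input, and the output head is
zero-initialised, so the whole reverse chain starts as the identity map
and corrections grow only where the loss demands them; otherwise the
network's idle output fluctuations dwarf the small useful correction each
step must make and accumulate over the chain.
Adam uses lr $3 \times 10^{-3}$, $\beta = (0.9, 0.999)$, gradient
accumulation over batches of 2.

## Stage 2 model

The restored (or clean) frame is tokenised into non-overlapping square
patches (default 4 x 4 at desk resolution; 8 x 8 suits the native
resolution), linearly embedded with a learned positional embedding
(zero-initialised, so the 0-layer encoder is exactly the patch embedding),
and passed through pre-norm transformer blocks
(LN - self-attention - residual, LN - MLP - residual). The token grid is
then upsampled by `decoder_blocks` repetitions of stride-2 transposed
convolution + batch normalisation + ReLU, flattened, and mapped by one
affine layer to $J \times 3 = 36$ coordinates. The keypoint count times
three, rather than a 12-vector, is forced by the per-joint 3D error
metrics; $J$ stays configurable. Keypoint targets are standardised per
coordinate during training and un-standardised at prediction, which makes
the learned bias the training mean pose — the natural constant baseline
that any useful model must beat.

## Metrics

* **PSNR** $= 10 \log_{10}(\mathrm{MAX}_I^2 / \mathrm{MSE})$ with
  $\mathrm{MAX}_I$ defaulting to the 15 kPa sensor ceiling — frames are
  physical quantities, not 8-bit images; identical frames report `Inf`.
* **SSIM** with the community-standard 11 x 11 Gaussian window
  ($\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$), weighted local moments and
  no sample-size correction; validated against an independent reference
  implementation.
* **MAE** in the frame's native pressure unit.
* **Perceptual distance**: layer-weighted mean squared distance between
  per-position unit-normalised feature maps. The published form of this
  metric uses a pretrained backbone; the built-in extractor is a
  deterministic fixed-seed two-layer convolutional network, so values are
  reproducible offline but not comparable to published perceptual scores.
  A pretrained extractor can be passed in where comparability matters.
* **MPJPE**: mean Euclidean keypoint error (mm). The printed definition
  sums over joints without dividing by $J$; the package defaults to the
  conventional $1/(NJ)$ normalisation — the millimetre scale of reported
  pose errors implies per-joint averaging — and keeps the sum-over-joints
  variant behind `per_joint_mean = FALSE`.
* **AKLEB**: per-axis (X, Y, Z) mean absolute coordinate error (mm).

## The synthetic scene generator

Real recordings pair the mat with a motion-capture system; neither is
available to an offline test suite, so the generator emulates the study
conditions end to end:

* **Poses.** Twelve activity templates (standing, squat, plank, lunges,
  sitting variants, bends, goddess, wide fold, walking, extended legs) in
  mm, with seeded global placement and per-joint jitter; joints in ground
  contact are pinned to $z = 0$ exactly. Coordinates: x along the mat's
  1.80 m axis, y across its 0.60 m, z up, origin at the mat corner, frames
  row-major with row 1 at the top.
* **Rendering.** Each contact joint contributes an anisotropic Gaussian
  pressure blob ($\sigma$ = 90 mm along the mat, 45 mm across — elongated
  like a foot) centred at its mat projection; the body weight (70 kg) is
  shared equally among contacts so integrated pressure is proportional to
  weight, and values are clipped at the 15 kPa ceiling. Blobs are
  anisotropic rather than isotropic because desk-scale grids have strongly
  anisotropic pixel pitch; an isotropic-in-mm contact cannot both survive
  the mask opening and keep the two feet separate at 160 x 96, while the
  elongated contact does both and is closer to a real foot print.
* **Corruption.** Additive zero-mean Gaussian sensor noise
  ($\sigma$ = 0.5 kPa) plus a Poisson number (mean 3) of spurious small
  blobs (support below the opening kernel, amplitude 2-6 kPa), clipped to
  $[0, 15]$ kPa. These defaults are fixed properties of the emulated
  sensor, not tuning knobs.
* **Pairing and splits.** Timestamps at the 60 Hz frame period with exact
  frame-keypoint pairing; held-out *activities* (sitting and squatting by
  default) form an activity-disjoint validation split, while the remaining
  activities are split 80/20 frame-wise into train/test.

What the generator does **not** emulate: biomechanically valid force
distributions, soft-tissue deformation, temporal correlation of noise, the
two stacked sensing layers of the real mat, or inter-subject variation.
Passing tests therefore demonstrate that the pipeline's machinery works and
improves its inputs under controlled conditions, not that it reaches any
particular accuracy on real recordings.

## Problem sizes and numerical choices

The package's own experiments run at deliberately small scale: 32 x 20
frames (16 x 8 tactel grid), $D = 10$, U-Net depth 2 with 8 base channels,
a 1-2 block transformer of width 16-32, a few hundred scenes and a handful
of epochs. These sizes are the package's chosen desk-scale study
conditions; the architecture is resolution-independent and scales to the
native 496 x 298 geometry by the configuration objects alone. The
160 x 96 resolution is used where mask-refinement geometry matters, since
the 5 x 5 opening is calibrated to fine grids. Two defaults scale with the
frame: the attention key/value pooling is 2 at 32 x 20 (the default 4
suits fine grids; coarse pooling at coarse resolution leaves the mask
stream too blurry to out-perform the pressure-only variant), and the patch
side is 4 because the frame sides must be divisible by it (8 divides
neither 20 nor 298).

Other numerical choices: all randomness flows from one root seed through a
counter-hash (`derive_seed()`), so every run is bitwise reproducible;
Otsu's threshold returns an empty mask for all-zero frames; attention
logits are max-shifted before the softmax; layer/batch normalisation uses
$\epsilon = 10^{-5}$, batch-norm running statistics use momentum 0.1;
`reverse_denoise` with a degenerate $D = 0$ schedule returns the clipped
input unchanged. Gradients of every layer are verified against central
finite differences in the test suite, and attention, dilated convolution
and transposed convolution are checked against explicit-loop oracles.

## Known limitations

* Reverse denoising is deterministic (no ancestral sampling); restoration
  quality at desk scale depends on the contractive training mix described
  above.
* The perceptual metric's built-in backbone is random-featured; absolute
  values are not comparable to published numbers.
* The real recording format of the mat is undocumented; readers and writers
  implement the package's own documented CSV/JSON layout, with timestamp
  pairing (exact or nearest-within-tolerance) as the adapter point.
* Published full-scale accuracies require the real dataset and GPU-scale
  training of far larger models; nothing at desk scale is expected to
  reproduce them, and the package does not attempt to.
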