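# tactpose

Non-intrusive 3D posture estimation from a pressure-sensitive floor mat.
`tactpose` restores sparse, noisy tactile pressure frames with a
dual-diffusion enhancement model and regresses 12 body keypoints
(millimetres) from the restored frame with a transformer–convolution
network. It is aimed at researchers working on tactile human-motion
analysis who need a fully reproducible, CPU-scale implementation of the
two-stage pipeline, including a synthetic scene generator that emulates the
sensor, so everything runs without proprietary recordings.

## The method

A mat frame is a grid `P` of pressures (kPa, ceiling 15) that is sparse
(only contact blobs carry signal) and corrupted: `P = P_true + N`. Stage 1
estimates `P_true`; stage 2 maps it to keypoints `C = f(P_true)`.

**Stage 1 — dual-diffusion signal enhancement.** A binary foreground mask
is produced from the raw frame by thresholding and a morphological opening
(3 erosions + 3 dilations, solid 5×5 kernel) that provably removes blobs
smaller than the kernel. Frame and mask then undergo parallel forward
diffusion with a shared linear-decay schedule,

    x_t = sqrt(alpha_t) x_{t-1} + sqrt(1 - alpha_t) eps_t,   t = 1..D,

turning the binary mask into a soft mask. A U-Net denoiser, entered
through a contour detection and alignment (CDA) layer — 3×3 atrous
convolutions at rates 2, 4, 6, 8 over the mask stream, fused into the
pressure stream by spatially pooled multi-head cross-attention — then runs
the reverse recursion `P_{t-1} = U(P_t, M_t, t)` from `t = D` down to 1,
conditioned at each step on the stored diffused mask.

**Stage 2 — pose transformer.** The restored frame is patch-tokenised,
encoded by pre-norm transformer blocks (`LN → self-attention`,
`LN → MLP`, residuals), upsampled by stride-2 deconvolution + batch norm +
ReLU blocks, flattened, and mapped by one affine layer to `J × 3 = 36`
coordinates.

Restoration is scored by PSNR, SSIM, MAE and a perceptual feature
distance; poses by MPJPE (mean per-joint Euclidean error, mm) and AKLEB
(per-axis mean absolute error, mm). The methods vignette
(`vignettes/tactpose-methods.Rmd`) derives the closed-form diffusion
marginals, documents every tunable with its default, and explains the
desk-scale design choices.

## Worked example

```r
library(tactpose)

cfg  <- scene_config(grid_h = 16, grid_w = 8, frame_h = 32, frame_w = 20,
                     spurious_blob_size = 2, seed = 11)
ds   <- make_dataset(310, cfg, body_model(), val_activities = c("sit", "squat"))
sched <- make_schedule(10, 0.99995, 0.9999)
mask  <- mask_params(kernel = 3, n_erosions = 1, n_dilations = 1)
ucfg  <- unet_config(depth = 2, base_channels = 8,
                     cda = cda_config(channels = 8, pool_size = 2, n_heads = 2))

tr  <- which(ds$split$split == "train")[1:200]
fit <- train_stage1(ds$scenes[tr], sched, mask, cfg = ucfg, epochs = 5, seed = 1)

te       <- which(ds$split$split == "test")[1:20]
restored <- lapply(te, function(i)
  reverse_denoise(ds$scenes[[i]]$noisy, sched, mask, fit$model, rng_seed = i))
clean <- lapply(ds$scenes[te], `[[`, "clean")
noisy <- lapply(ds$scenes[te], `[[`, "noisy")
restoration_report(noisy, clean)
#> # A tibble: 1 x 5
#>   psnr_db  ssim   mae lpips n_frames
#>     <dbl> <dbl> <dbl> <dbl>    <int>
#> 1    27.8 0.616 0.309 0.546       20
restoration_report(restored, clean)
#> # A tibble: 1 x 5
#>   psnr_db  ssim   mae lpips n_frames
#>     <dbl> <dbl> <dbl> <dbl>    <int>
#> 1    32.2 0.894 0.176 0.593       20
```

Training takes about two minutes on one CPU core; restoring a frame runs
ten reverse steps. Restoration gains about 4.4 dB of PSNR and lifts SSIM
from 0.62 to 0.89 on these held-out frames (all 20 improve), because the
learned chain removes the sensor noise and the spurious small blobs while
the refined-mask stream keeps the genuine contact areas untouched. (The
perceptual-distance column uses the built-in random-feature extractor and
is reproducible but not comparable to published perceptual scores.)
Stage 2 follows the same pattern with `train_stage2()` /
`predict_pose()`, and `run_ablation()` tabulates the architecture variants
(pressure-stream only; + mask stream and cross-attention; + pyramidal
pooling).

A thin command-line front end ships in `inst/exec/tactpose`
(`simulate`, `train-stage1`, `restore`, `train-stage2`, `predict`,
`evaluate`, `ablation`).

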