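Package: tactpose
Title: Tactile Pressure-Map Restoration and 3D Posture Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage pipeline for estimating 3D human body keypoints from
    noisy, sparse pressure maps recorded by a floor-mat tactile sensor array.
    Stage one restores the pressure signal with a dual-forward-diffusion
    enhancement model: the frame and a morphologically refined foreground mask
    are diffused in parallel and denoised by a small U-Net whose entrance
    fuses mask contours into the pressure stream through atrous pyramidal
    pooling and spatially pooled cross-attention. Stage two regresses the 12
    body keypoints (millimetres) from the restored frame with a
    transformer-convolution network. Includes a synthetic scene generator
    emulating the sensor geometry (pressure ceiling, sensor noise, spurious
    blobs, timestamp-paired motion-capture labels), restoration metrics
    (PSNR, SSIM, MAE, perceptual distance) and pose metrics (MPJPE, per-axis
    keypoint error), dataset readers and writers, and an ablation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    ggplot2,
    png,
    optparse
Config/testthat/edition: 3
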