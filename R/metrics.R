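# Evaluation metrics: restoration quality (PSNR, SSIM, MAE, perceptual
# distance) and pose accuracy (MPJPE, per-axis keypoint error), plus tibble
# report helpers.

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(max_i^2 / MSE)`. Identical inputs give `Inf`.
#'
#' @param x,y same-shape numeric matrices.
#' @param max_i maximum possible value of the signal (for pressure frames the
#'   sensor ceiling, 15 kPa, rather than 255).
#' @return scalar dB value.
#' @export
psnr <- function(x, y, max_i = 15) {
  check_same_shape(x, y)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_i^2 / mse)
}

gaussian_window <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 2D "valid" correlation of x with window w (small w, loop over its support)
filter_valid <- function(x, w) {
  k <- nrow(w)
  H <- nrow(x) - k + 1; W <- ncol(x) - k + 1
  out <- matrix(0, H, W)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    out <- out + w[a, b] * x[a:(a + H - 1), b:(b + W - 1)]
  }
  out
}

#' Structural similarity index
#'
#' Mean of the local SSIM map over sliding Gaussian-weighted windows
#' (defaults: 11 x 11, sigma 1.5, k1 = 0.01, k2 = 0.03), with weighted local
#' moments and no sample-size correction.
#'
#' @param x,y same-shape matrices.
#' @param max_i dynamic range of the signal.
#' @param window odd window side.
#' @param k1,k2 stabilising constants; `c1 = (k1*max_i)^2`, `c2 = (k2*max_i)^2`.
#' @param sigma Gaussian window sd (pixels).
#' @return scalar in (-1, 1].
#' @export
ssim <- function(x, y, max_i = 15, window = 11, k1 = 0.01, k2 = 0.03,
                 sigma = 1.5) {
  check_same_shape(x, y)
  if (window > min(dim(x))) {
    stop_("window (%d) larger than image (%dx%d)", window, nrow(x), ncol(x))
  }
  w <- gaussian_window(window, sigma)
  c1 <- (k1 * max_i)^2; c2 <- (k2 * max_i)^2
  mx <- filter_valid(x, w); my <- filter_valid(y, w)
  sxx <- filter_valid(x * x, w) - mx^2
  syy <- filter_valid(y * y, w) - my^2
  sxy <- filter_valid(x * y, w) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Mean absolute error
#'
#' @param x,y same-shape matrices.
#' @return nonnegative scalar in the frames' native unit.
#' @export
mae <- function(x, y) {
  check_same_shape(x, y)
  mean(abs(x - y))
}

#' Built-in fixed-seed convolutional feature extractor
#'
#' A deterministic two-layer random 3x3 convolutional network used as the
#' backbone of [lpips_like()] when no pretrained extractor is supplied.
#'
#' @param channels channels per layer.
#' @param seed weight seed.
#' @return object of class `lpips_extractor`: a function mapping an `H x W`
#'   matrix to a list of `[H, W, C]` feature arrays.
#' @export
lpips_extractor <- function(channels = c(8, 16), seed = 7) {
  weights <- list()
  cin <- 1L
  for (l in seq_along(channels)) {
    weights[[l]] <- list(W = w_init(9 * cin, channels[l], derive_seed(seed, l)),
                         b = zeros_row(channels[l]))
    cin <- channels[l]
  }
  f <- function(x) {
    H <- nrow(x); W <- ncol(x)
    cur <- matrix(as.vector(x), ncol = 1)
    out <- vector("list", length(weights))
    for (l in seq_along(weights)) {
      idx <- conv_idx(H, W, 3, 1, ncol(cur))
      v <- c(as.vector(cur), 0)
      cols <- matrix(v[idx], nrow(idx), ncol(idx))
      cur <- cols %*% weights[[l]]$W
      cur <- cur + matrix(weights[[l]]$b, nrow(cur), ncol(cur), byrow = TRUE)
      cur <- pmax(cur, 0)
      out[[l]] <- mat_to_fm(cur, H, W)
    }
    out
  }
  structure(f, class = "lpips_extractor")
}

#' Perceptual feature distance
#'
#' Weighted sum over layers of the mean squared distance between per-position
#' unit-normalised feature vectors of the two inputs — the learned-feature
#' perceptual distance, here over a deterministic built-in extractor (a
#' pretrained backbone may be supplied for comparability with published
#' perceptual scores).
#'
#' @param x,y same-shape matrices.
#' @param extractor an [lpips_extractor()] (or compatible function).
#' @param weights per-layer weights.
#' @return nonnegative scalar, 0 for identical inputs.
#' @export
lpips_like <- function(x, y, extractor = lpips_extractor(),
                       weights = NULL) {
  check_same_shape(x, y)
  if (!is.function(extractor)) {
    stop_("extractor unavailable; pass lpips_extractor() (the built-in fixed-seed convolutional extractor) or a compatible function")
  }
  fx <- extractor(x); fy <- extractor(y)
  if (is.null(weights)) weights <- rep(1 / length(fx), length(fx))
  unit_norm <- function(fm) {
    m <- fm_to_mat(fm)
    nrm <- sqrt(rowSums(m^2)) + 1e-10
    m / nrm
  }
  total <- 0
  for (l in seq_along(fx)) {
    dx <- unit_norm(fx[[l]]) - unit_norm(fy[[l]])
    total <- total + weights[l] * mean(rowSums(dx^2))
  }
  total
}

as_pose_array <- function(p) {
  if (is.matrix(p)) array(unclass(p)[, , drop = FALSE], c(1, dim(p))) else p
}

#' Mean per-joint position error (mm)
#'
#' Average Euclidean distance between predicted and ground-truth joint
#' positions. Default normalisation averages over samples and joints; the
#' `per_joint_mean = FALSE` variant sums over joints within a sample and
#' averages over samples only.
#'
#' @param pred,gt `J x 3` matrices or `[N, J, 3]` arrays (mm).
#' @param per_joint_mean divide by the number of joints (default TRUE).
#' @return nonnegative scalar (mm).
#' @export
mpjpe <- function(pred, gt, per_joint_mean = TRUE) {
  pred <- as_pose_array(pred); gt <- as_pose_array(gt)
  if (!identical(dim(pred), dim(gt))) stop_("pred and gt shapes differ")
  d <- sqrt(apply((pred - gt)^2, c(1, 2), sum))
  if (per_joint_mean) mean(d) else mean(rowSums(matrix(d, dim(pred)[1])))
}

#' Per-axis keypoint localisation error (mm)
#'
#' Mean absolute coordinate error per dimension, averaged over joints and
#' samples; one value for each of X, Y, Z.
#'
#' @inheritParams mpjpe
#' @return named numeric vector `c(X = , Y = , Z = )`.
#' @export
akleb <- function(pred, gt) {
  pred <- as_pose_array(pred); gt <- as_pose_array(gt)
  if (!identical(dim(pred), dim(gt))) stop_("pred and gt shapes differ")
  out <- apply(abs(pred - gt), 3, mean)
  names(out) <- c("X", "Y", "Z")
  out
}

#' Restoration quality report over frame pairs
#'
#' @param pred,gt lists of same-shape matrices (restored and clean frames).
#' @param max_i dynamic range for PSNR/SSIM.
#' @return one-row tibble: psnr_db, ssim, mae, lpips, n_frames.
#' @export
restoration_report <- function(pred, gt, max_i = 15) {
  stopifnot(length(pred) == length(gt))
  ex <- lpips_extractor()
  vals <- vapply(seq_along(pred), function(i) {
    c(psnr(pred[[i]], gt[[i]], max_i), ssim(pred[[i]], gt[[i]], max_i),
      mae(pred[[i]], gt[[i]]), lpips_like(pred[[i]], gt[[i]], ex))
  }, numeric(4))
  tibble::tibble(psnr_db = mean(vals[1, ]), ssim = mean(vals[2, ]),
                 mae = mean(vals[3, ]), lpips = mean(vals[4, ]),
                 n_frames = length(pred))
}

#' Pose accuracy report
#'
#' @param pred,gt `[N, J, 3]` arrays or lists of `J x 3` matrices (mm).
#' @return one-row tibble: mpjpe_mm, akleb X/Y/Z, n_samples, n_joints.
#' @export
pose_report <- function(pred, gt) {
  to_arr <- function(p) {
    if (is.list(p)) {
      arr <- array(0, c(length(p), dim(p[[1]])))
      for (i in seq_along(p)) arr[i, , ] <- p[[i]]
      arr
    } else as_pose_array(p)
  }
  pa <- to_arr(pred); ga <- to_arr(gt)
  ak <- akleb(pa, ga)
  tibble::tibble(mpjpe_mm = mpjpe(pa, ga), akleb_x = ak[["X"]],
                 akleb_y = ak[["Y"]], akleb_z = ak[["Z"]],
                 n_samples = dim(pa)[1], n_joints = dim(pa)[2])
}
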