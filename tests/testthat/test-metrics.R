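test_that("psnr matches closed-form cases and the infinity convention", {
  x <- rand_frame(16, 16, 1)
  expect_equal(psnr(x, x), Inf)
  # MSE constructed as max_i^2 / 10 gives exactly 10 dB
  y <- x + sqrt(15^2 / 10)
  expect_equal(psnr(x, y, max_i = 15), 10.0)
  # 8-bit style: constant error 16, MSE 256 -> 10*log10(255^2/256)
  a <- matrix(100, 10, 10); b <- matrix(116, 10, 10)
  expect_equal(psnr(a, b, max_i = 255), 10 * log10(255^2 / 256),
               tolerance = 1e-12)
  expect_equal(psnr(a, b, 255), 24.0535, tolerance = 1e-3)
  expect_error(psnr(x, matrix(0, 2, 2)), "dimensions")
})

test_that("ssim identities and the constant-image closed form hold", {
  x <- rand_frame(32, 32, 2)
  expect_equal(ssim(x, x, max_i = 1), 1.0)
  # zero-variance images: SSIM reduces to the luminance term
  a <- 0.3; b <- 0.7; c1 <- (0.01 * 1)^2
  expect_equal(ssim(matrix(a, 20, 20), matrix(b, 20, 20), max_i = 1),
               (2 * a * b + c1) / (a^2 + b^2 + c1), tolerance = 1e-12)
  expect_error(ssim(matrix(1, 5, 5), matrix(1, 5, 5), window = 11), "larger")
})

test_that("ssim and psnr agree with the independent reference implementation", {
  # fixture rebuilt from the seeded RNG; reference values computed once with
  # scikit-image structural_similarity (gaussian weights, sigma 1.5, 11x11,
  # K1=0.01, K2=0.03, no sample covariance) and peak_signal_noise_ratio
  set.seed(42)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- pmin(pmax(x + matrix(rnorm(32 * 32, 0, 0.1), 32, 32), 0), 1)
  expect_equal(ssim(x, y, max_i = 1), 0.9465330595144694, tolerance = 1e-4)
  expect_equal(psnr(x, y, max_i = 1), 20.605198795956895, tolerance = 1e-8)
})

test_that("ssim approaches 1 continuously for vanishing perturbations", {
  x <- rand_frame(24, 24, 3)
  vals <- vapply(c(1e-2, 1e-4, 1e-6), function(e) {
    ssim(x, x + e, max_i = 1)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3], 1 - 1e-8)
})

test_that("mae matches the explicit-loop oracle", {
  x <- rand_frame(12, 9, 4); y <- rand_frame(12, 9, 5)
  expect_equal(mae(x, x), 0)
  expect_equal(mae(x, x + 0.5), 0.5)
  acc <- 0
  for (i in 1:12) for (j in 1:9) acc <- acc + abs(x[i, j] - y[i, j])
  expect_equal(mae(x, y), acc / (12 * 9), tolerance = 1e-12)
})

test_that("perceptual distance identities and loop oracle", {
  x <- rand_frame(16, 12, 6); y <- rand_frame(16, 12, 7)
  ex <- lpips_extractor()
  expect_equal(lpips_like(x, x, ex), 0)
  expect_equal(lpips_like(x, y, ex, weights = c(0, 0)), 0)
  # explicit-loop distance over unit-normalised features
  fx <- ex(x); fy <- ex(y)
  total <- 0
  for (l in 1:2) {
    a <- fx[[l]]; b <- fy[[l]]
    npos <- dim(a)[1] * dim(a)[2]
    s <- 0
    for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2])) {
      va <- a[i, j, ]; vb <- b[i, j, ]
      va <- va / (sqrt(sum(va^2)) + 1e-10)
      vb <- vb / (sqrt(sum(vb^2)) + 1e-10)
      s <- s + sum((va - vb)^2)
    }
    total <- total + 0.5 * s / npos
  }
  expect_equal(lpips_like(x, y, ex), total, tolerance = 1e-5)
  expect_gte(lpips_like(x, y, ex), 0)
  expect_error(lpips_like(x, y, extractor = NULL), "extractor")
})

test_that("mpjpe matches hand cases and the double-loop oracle", {
  g <- matrix(c(0, 0, 0), 1, 3)
  p <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(mpjpe(p, g), 5.0) # 3-4-5 triangle
  expect_equal(mpjpe(g, g), 0)
  set.seed(9)
  N <- 7; J <- 12
  pr <- array(rnorm(N * J * 3, 0, 100), c(N, J, 3))
  gt <- array(rnorm(N * J * 3, 0, 100), c(N, J, 3))
  acc <- 0
  for (i in seq_len(N)) for (j in seq_len(J)) {
    acc <- acc + sqrt(sum((pr[i, j, ] - gt[i, j, ])^2))
  }
  expect_equal(mpjpe(pr, gt), acc / (N * J), tolerance = 1e-9)
  expect_equal(mpjpe(pr, gt, per_joint_mean = FALSE), acc / N, tolerance = 1e-9)
})

test_that("akleb is the per-axis mean absolute error", {
  g <- array(0, c(2, 5, 3))
  p <- g; p[, , 2] <- 2 # uniform +2 mm shift in Y
  expect_equal(akleb(p, g), c(X = 0, Y = 2, Z = 0))
  expect_equal(akleb(g, g), c(X = 0, Y = 0, Z = 0))
  set.seed(10)
  pr <- array(rnorm(60), c(4, 5, 3)); gt <- array(rnorm(60), c(4, 5, 3))
  ref <- numeric(3)
  for (d in 1:3) ref[d] <- mean(abs(pr[, , d] - gt[, , d]))
  expect_equal(unname(akleb(pr, gt)), ref, tolerance = 1e-12)
})

test_that("restoration and pose metrics are symmetric where expected", {
  x <- rand_frame(20, 20, 11); y <- rand_frame(20, 20, 12)
  expect_equal(psnr(x, y, 1), psnr(y, x, 1))
  expect_equal(ssim(x, y, 1), ssim(y, x, 1), tolerance = 1e-12)
  expect_equal(mae(x, y), mae(y, x))
  ex <- lpips_extractor()
  expect_equal(lpips_like(x, y, ex), lpips_like(y, x, ex), tolerance = 1e-12)
  # mpjpe dominates each per-axis absolute error component
  set.seed(13)
  pr <- array(rnorm(90), c(3, 10, 3)); gt <- array(rnorm(90), c(3, 10, 3))
  expect_gte(mpjpe(pr, gt), max(akleb(pr, gt)))
})

test_that("report helpers aggregate into tibbles", {
  x <- list(rand_frame(16, 16, 1), rand_frame(16, 16, 2))
  y <- list(rand_frame(16, 16, 3), rand_frame(16, 16, 4))
  r <- restoration_report(x, y, max_i = 1)
  expect_s3_class(r, "tbl_df")
  expect_equal(r$n_frames, 2)
  expect_true(all(is.finite(c(r$psnr_db, r$ssim, r$mae, r$lpips))))
  pr <- list(matrix(rnorm(36), 12, 3), matrix(rnorm(36), 12, 3))
  pp <- pose_report(pr, pr)
  expect_equal(pp$mpjpe_mm, 0)
  expect_equal(pp$n_joints, 12)
})
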