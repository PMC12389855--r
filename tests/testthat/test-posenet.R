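test_that("zero-layer encoder reduces to the patch embedding", {
  pcfg <- posenet_config(patch_size = 4, d_model = 8, n_layers = 0,
                         n_heads = 2, n_joints = 3)
  model <- init_posenet(pcfg, 16, 8, seed = 1)
  x <- rand_frame(16, 8, 2)
  tok <- encode(x, model)
  idx <- tactpose:::patch_idx(16, 8, 4)
  xv <- as.vector(x)
  patches <- matrix(xv[idx], nrow(idx), ncol(idx))
  ref <- patches %*% model$params[["patch.W"]]
  ref <- ref + matrix(model$params[["patch.b"]], nrow(ref), 8, byrow = TRUE)
  expect_equal(tok, ref, tolerance = 1e-12)
})

test_that("encoder attention rows are normalised and output is equivariant", {
  pcfg <- posenet_config(patch_size = 4, d_model = 8, n_layers = 2,
                         n_heads = 2, n_joints = 3)
  model <- init_posenet(pcfg, 16, 8, seed = 5)
  model$params[["pos"]] <- tactpose:::with_seed(6, matrix(rnorm(8 * 8, 0, 0.1), 8, 8))
  x <- rand_frame(16, 8, 3)
  res <- encode(x, model, return_attn = TRUE)
  for (layer in res$attn) for (A in layer) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
  # permuting tokens together with their positional embeddings permutes output
  perm <- tactpose:::with_seed(7, sample.int(8))
  idx <- tactpose:::patch_idx(16, 8, 4)
  xv <- as.vector(x)
  patches <- matrix(xv[idx], nrow(idx), ncol(idx))
  emb <- patches %*% model$params[["patch.W"]]
  emb <- emb + matrix(model$params[["patch.b"]], 8, 8, byrow = TRUE)
  run_tokens <- function(emb0, pos) {
    mdl <- model
    mdl$params[["pos"]] <- pos
    tape <- tactpose:::tp_new()
    bind <- tactpose:::make_binder(tape, mdl$params)
    tok <- tactpose:::op_add(tape, tactpose:::tp_const(tape, emb0), bind("pos"))
    for (l in 1:2) {
      pre <- sprintf("enc%d", l)
      h <- tactpose:::op_layernorm_rows(tape, tok, bind(paste0(pre, ".ln1.g")),
                                        bind(paste0(pre, ".ln1.b")))
      sa <- tactpose:::mha(tape, h, h, bind, paste0(pre, ".attn"), 2)
      tok <- tactpose:::op_add(tape, tok, sa$out)
      h <- tactpose:::op_layernorm_rows(tape, tok, bind(paste0(pre, ".ln2.g")),
                                        bind(paste0(pre, ".ln2.b")))
      m1 <- tactpose:::op_relu(tape, tactpose:::op_addvec(tape,
              tactpose:::op_matmul(tape, h, bind(paste0(pre, ".mlp.W1"))),
              bind(paste0(pre, ".mlp.b1"))))
      m2 <- tactpose:::op_addvec(tape,
              tactpose:::op_matmul(tape, m1, bind(paste0(pre, ".mlp.W2"))),
              bind(paste0(pre, ".mlp.b2")))
      tok <- tactpose:::op_add(tape, tok, m2)
    }
    tok$value
  }
  base <- run_tokens(emb, model$params[["pos"]])
  permuted <- run_tokens(emb[perm, ], model$params[["pos"]][perm, ])
  expect_equal(permuted, base[perm, ], tolerance = 1e-10)
})

test_that("decoder doubles spatial size, is nonnegative, and matches the deconv oracle", {
  pcfg <- posenet_config(patch_size = 4, d_model = 8, n_layers = 0,
                         n_heads = 2, decoder_blocks = 1, n_joints = 3)
  model <- init_posenet(pcfg, 8, 8, seed = 3) # 2x2 token grid
  tok <- tactpose:::with_seed(4, matrix(rnorm(4 * 8), 4, 8))
  out <- decode(tok, model)
  expect_equal(dim(out), c(4, 4, 4))
  expect_true(all(out >= 0))
  # brute-force 2x2-stride-2 transposed convolution on the 2x2 token grid
  Wd <- model$params[["dec1.up.W"]] # [8, 4*4]
  pre <- array(0, c(4, 4, 4))
  for (i in 1:2) for (j in 1:2) {
    tv <- tok[i + (j - 1) * 2, ]
    for (o in 1:4) for (b in 1:2) for (a in 1:2) {
      q <- (o - 1) * 4 + (b - 1) * 2 + a
      pre[2 * (i - 1) + a, 2 * (j - 1) + b, o] <-
        pre[2 * (i - 1) + a, 2 * (j - 1) + b, o] + sum(tv * Wd[, q])
    }
  }
  pre <- sweep(pre, 3, as.vector(model$params[["dec1.up.b"]]), "+")
  # batch norm (eval stats mean 0 var 1) + ReLU
  g <- as.vector(model$params[["dec1.bn.g"]]); be <- as.vector(model$params[["dec1.bn.b"]])
  ref <- pre
  for (o in 1:4) ref[, , o] <- pmax(pre[, , o] / sqrt(1 + 1e-5) * g[o] + be[o], 0)
  expect_lt(max(abs(out - ref)), 1e-5)
})

test_that("keypoint head is the documented affine map", {
  pcfg <- posenet_config(patch_size = 4, d_model = 8, n_layers = 0,
                         n_heads = 2, decoder_blocks = 1, n_joints = 2)
  model <- init_posenet(pcfg, 8, 8, seed = 9)
  k <- array(tactpose:::with_seed(10, abs(rnorm(4 * 4 * 4))), c(4, 4, 4))
  # W = 0 -> prediction is b (un-standardised)
  m0 <- model
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]] <- matrix(1:6, 1)
  expect_equal(as.vector(t(predict_keypoints(k, m0))), 1:6)
  # linearity: doubling W doubles (output - b)
  m1 <- model
  base <- predict_keypoints(k, m1)
  m2 <- m1; m2$params[["head.W"]] <- 2 * m1$params[["head.W"]]
  b_resh <- matrix(as.vector(m1$params[["head.b"]]), 2, 3, byrow = TRUE)
  expect_equal(predict_keypoints(k, m2) - b_resh, 2 * (base - b_resh),
               tolerance = 1e-10)
  # dot-product oracle on a small feature
  mS <- init_posenet(posenet_config(patch_size = 2, d_model = 4, n_layers = 0,
                                    n_heads = 2, decoder_blocks = 0,
                                    n_joints = 1), 2, 2, seed = 2)
  kf <- array(c(0.3, -0.2, 0.5, 0.1), c(1, 1, 4))
  v <- as.vector(kf)
  expect_equal(as.vector(predict_keypoints(kf, mS)),
               as.vector(v %*% mS$params[["head.W"]] + mS$params[["head.b"]]),
               tolerance = 1e-6)
})

test_that("stage-2 training beats the mean-pose baseline on held-out activities", {
  cfg <- tiny_scene_cfg(seed = 21)
  ds <- make_dataset(160, cfg, body_model(), val_activities = c("sit", "squat"))
  tr <- which(ds$split$split == "train")
  va <- which(ds$split$split == "val")
  pcfg <- posenet_config(patch_size = 4, d_model = 16, n_layers = 1,
                         n_heads = 2, decoder_blocks = 1)
  mpj_model <- numeric(2); mpj_base <- numeric(2)
  for (s in 1:2) {
    fit <- train_stage2(ds$scenes[tr], pcfg, epochs = 4, seed = s)
    preds <- lapply(va, function(i) predict_pose(ds$scenes[[i]]$clean, fit$model))
    gts <- lapply(va, function(i) unclass(ds$scenes[[i]]$pose)[, 1:3])
    mpj_model[s] <- pose_report(preds, gts)$mpjpe_mm
    mpj_base[s] <- pose_report(rep(list(fit$mean_pose), length(va)), gts)$mpjpe_mm
  }
  expect_lt(median(mpj_model), median(mpj_base))
  # training loss decreased in trend
  fit <- train_stage2(ds$scenes[tr], pcfg, epochs = 4, seed = 3)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("zero learning rate freezes the stage-2 loss", {
  cfg <- tiny_scene_cfg(seed = 22)
  ds <- make_dataset(20, cfg, body_model(), val_activities = character(0))
  fit <- train_stage2(ds$scenes[1:12], posenet_config(patch_size = 4,
                        d_model = 8, n_layers = 1, n_heads = 2),
                      lr = 0, epochs = 3, seed = 1)
  expect_equal(diff(range(fit$history$loss)), 0, tolerance = 1e-12)
})

test_that("pose model predictions are deterministic and checkpoint round-trips bitwise", {
  cfg <- tiny_scene_cfg(seed = 23)
  ds <- make_dataset(24, cfg, body_model(), val_activities = character(0))
  fit <- train_stage2(ds$scenes[1:16], posenet_config(patch_size = 4,
                        d_model = 8, n_layers = 1, n_heads = 2),
                      epochs = 2, seed = 4)
  x <- ds$scenes[[20]]$clean
  p1 <- predict_pose(x, fit$model)
  expect_identical(p1, predict_pose(x, fit$model))
  expect_true(all(is.finite(p1)))
  expect_equal(dim(p1), c(12, 3))
  path <- tempfile(fileext = ".rds")
  save_model(fit$model, path)
  expect_identical(predict_pose(x, load_model(path)), p1)
})
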