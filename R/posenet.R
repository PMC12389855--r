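# Stage 2: transformer encoder over the (restored) pressure frame, a
# deconvolution decoder, and a linear keypoint head regressing the 12 body
# keypoints in millimetres. Keypoint targets are standardised per coordinate
# during training and un-standardised at prediction.

#' Pose network configuration
#'
#' @param patch_size square patch side for tokenisation; frame dims must be
#'   divisible by it.
#' @param d_model token width.
#' @param n_layers transformer encoder blocks (pre-norm: LN -> self-attention
#'   -> residual, LN -> MLP -> residual).
#' @param n_heads attention heads; must divide `d_model`.
#' @param decoder_blocks stride-2 deconvolution + batch norm + ReLU blocks.
#' @param n_joints number of body keypoints.
#' @param mlp_mult MLP hidden width multiplier.
#' @return object of class `posenet_config`.
#' @export
posenet_config <- function(patch_size = 4, d_model = 32, n_layers = 2,
                           n_heads = 4, decoder_blocks = 1, n_joints = 12,
                           mlp_mult = 2) {
  if (d_model %% n_heads != 0) stop_("d_model must be divisible by n_heads")
  structure(list(patch_size = as.integer(patch_size),
                 d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 decoder_blocks = as.integer(decoder_blocks),
                 n_joints = as.integer(n_joints),
                 mlp_mult = as.integer(mlp_mult)),
            class = "posenet_config")
}

# gather index regrouping an [H*W, 1] frame into [n_tokens, patch^2]
patch_idx <- function(H, W, ps) {
  key <- paste("patch", H, W, ps, sep = "_")
  cache_get(key, function() {
    Ht <- H %/% ps; Wt <- W %/% ps
    idx <- matrix(0L, Ht * Wt, ps * ps)
    q <- 0L
    for (b in seq_len(ps)) for (a in seq_len(ps)) {
      q <- q + 1L
      ti <- rep(seq_len(Ht), Wt)
      tj <- rep(seq_len(Wt), each = Ht)
      idx[, q] <- ((ti - 1L) * ps + a) + ((tj - 1L) * ps + b - 1L) * H
    }
    idx
  })
}

dec_channels <- function(cfg) {
  ch <- cfg$d_model
  vapply(seq_len(cfg$decoder_blocks), function(k) {
    ch <<- max(ch %/% 2L, 4L)
    ch
  }, integer(1))
}

#' Initialise a pose-network model
#'
#' @param cfg a [posenet_config()].
#' @param H,W input frame dimensions (must be divisible by `patch_size`).
#' @param seed init seed.
#' @return object of class `posenet_model`.
#' @export
init_posenet <- function(cfg = posenet_config(), H, W, seed = 1) {
  if (H %% cfg$patch_size != 0 || W %% cfg$patch_size != 0) {
    stop_("frame %dx%d not divisible by patch_size %d", H, W, cfg$patch_size)
  }
  ps <- cfg$patch_size; d <- cfg$d_model
  Ht <- H %/% ps; Wt <- W %/% ps
  n_tok <- Ht * Wt
  p <- list()
  p[["patch.W"]] <- w_init(ps * ps, d, derive_seed(seed, "patch"),
                           scale = sqrt(1 / (ps * ps)))
  p[["patch.b"]] <- zeros_row(d)
  p[["pos"]] <- matrix(0, n_tok, d) # zero-init: the 0-layer encoder is the patch embedding
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d", l)
    p[[paste0(pre, ".ln1.g")]] <- ones_row(d)
    p[[paste0(pre, ".ln1.b")]] <- zeros_row(d)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(pre, ".attn.", nm)]] <- w_init(d, d, derive_seed(seed, l, nm),
                                               scale = sqrt(1 / d))
    }
    for (nm in c("bq", "bk", "bv", "bo")) {
      p[[paste0(pre, ".attn.", nm)]] <- zeros_row(d)
    }
    p[[paste0(pre, ".ln2.g")]] <- ones_row(d)
    p[[paste0(pre, ".ln2.b")]] <- zeros_row(d)
    hid <- d * cfg$mlp_mult
    p[[paste0(pre, ".mlp.W1")]] <- w_init(d, hid, derive_seed(seed, l, "W1"))
    p[[paste0(pre, ".mlp.b1")]] <- zeros_row(hid)
    p[[paste0(pre, ".mlp.W2")]] <- w_init(hid, d, derive_seed(seed, l, "W2"),
                                          scale = sqrt(1 / hid))
    p[[paste0(pre, ".mlp.b2")]] <- zeros_row(d)
  }
  chs <- dec_channels(cfg)
  prev <- d
  bn_stats <- list()
  for (k in seq_len(cfg$decoder_blocks)) {
    p[[sprintf("dec%d.up.W", k)]] <- w_init(prev, 4 * chs[k],
                                            derive_seed(seed, "dec", k),
                                            scale = sqrt(2 / prev))
    p[[sprintf("dec%d.up.b", k)]] <- zeros_row(chs[k])
    p[[sprintf("dec%d.bn.g", k)]] <- ones_row(chs[k])
    p[[sprintf("dec%d.bn.b", k)]] <- zeros_row(chs[k])
    bn_stats[[k]] <- list(mean = rep(0, chs[k]), var = rep(1, chs[k]), n = 0)
    prev <- chs[k]
  }
  Hd <- Ht * 2^cfg$decoder_blocks; Wd <- Wt * 2^cfg$decoder_blocks
  flat <- Hd * Wd * prev
  p[["head.W"]] <- w_init(flat, 3 * cfg$n_joints, derive_seed(seed, "head"),
                          scale = sqrt(1 / flat))
  p[["head.b"]] <- zeros_row(3 * cfg$n_joints)
  structure(list(cfg = cfg, H = H, W = W, Ht = Ht, Wt = Wt,
                 params = p, bn_stats = bn_stats,
                 target_mean = rep(0, 3 * cfg$n_joints),
                 target_sd = rep(1, 3 * cfg$n_joints),
                 max_value = 15),
            class = "posenet_model")
}

# transformer encoder on the tape: frame [HW, 1] -> tokens [n_tok, d]
encode_node <- function(tape, bind, x, model) {
  cfg <- model$cfg
  tok <- op_gather(tape, x, patch_idx(model$H, model$W, cfg$patch_size))
  tok <- op_addvec(tape, op_matmul(tape, tok, bind("patch.W")), bind("patch.b"))
  tok <- op_add(tape, tok, bind("pos"))
  attn_all <- list()
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d", l)
    h <- op_layernorm_rows(tape, tok, bind(paste0(pre, ".ln1.g")),
                           bind(paste0(pre, ".ln1.b")))
    sa <- mha(tape, h, h, bind, paste0(pre, ".attn"), cfg$n_heads)
    attn_all[[l]] <- sa$attn
    tok <- op_add(tape, tok, sa$out)
    h <- op_layernorm_rows(tape, tok, bind(paste0(pre, ".ln2.g")),
                           bind(paste0(pre, ".ln2.b")))
    m1 <- op_relu(tape, op_addvec(tape, op_matmul(tape, h, bind(paste0(pre, ".mlp.W1"))),
                                  bind(paste0(pre, ".mlp.b1"))))
    m2 <- op_addvec(tape, op_matmul(tape, m1, bind(paste0(pre, ".mlp.W2"))),
                    bind(paste0(pre, ".mlp.b2")))
    tok <- op_add(tape, tok, m2)
  }
  list(tok = tok, attn = attn_all)
}

# decoder on the tape: tokens [n_tok, d] -> feature map node [Hd*Wd, C]
decode_node <- function(tape, bind, tok, model, training = FALSE) {
  cfg <- model$cfg
  h <- model$Ht; w <- model$Wt
  cur <- tok
  new_stats <- list()
  for (k in seq_len(cfg$decoder_blocks)) {
    cur <- layer_deconv2(tape, cur, bind(sprintf("dec%d.up.W", k)),
                         bind(sprintf("dec%d.up.b", k)), h, w)
    h <- 2L * h; w <- 2L * w
    if (training) {
      v <- cur$value
      mu <- colMeans(v)
      new_stats[[k]] <- list(mean = mu, var = colMeans(sweep(v, 2, mu)^2))
      cur <- op_batchnorm_cols(tape, cur, bind(sprintf("dec%d.bn.g", k)),
                               bind(sprintf("dec%d.bn.b", k)))
    } else {
      cur <- op_batchnorm_cols(tape, cur, bind(sprintf("dec%d.bn.g", k)),
                               bind(sprintf("dec%d.bn.b", k)),
                               stats = model$bn_stats[[k]])
    }
    cur <- op_relu(tape, cur)
  }
  list(fm = cur, H = h, W = w, new_stats = new_stats)
}

head_node <- function(tape, bind, fm) {
  flat <- tp_op(tape, matrix(as.vector(fm$value), 1), list(fm),
                function(g) list(matrix(as.vector(g), nrow(fm$value))))
  op_addvec(tape, op_matmul(tape, flat, bind("head.W")), bind("head.b"))
}

#' Transformer-encode a pressure frame into tokens
#'
#' Patch tokenisation with a learned positional embedding, then `n_layers`
#' pre-norm transformer blocks. With `n_layers = 0` (and the zero-initialised
#' positional embedding) the output is the patch embedding itself.
#'
#' @param p `H x W` frame matching the model's dimensions.
#' @param model a [init_posenet()] model.
#' @param return_attn also return per-layer, per-head attention matrices.
#' @return `[n_tokens, d_model]` matrix (or list with `tokens`, `attn`).
#' @export
encode <- function(p, model, return_attn = FALSE) {
  if (nrow(p) != model$H || ncol(p) != model$W) {
    stop_("frame %dx%d does not match model %dx%d",
          nrow(p), ncol(p), model$H, model$W)
  }
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  res <- encode_node(tape, bind, tp_const(tape, matrix(as.vector(p), ncol = 1)),
                     model)
  if (return_attn) list(tokens = res$tok$value, attn = res$attn)
  else res$tok$value
}

#' Decode tokens to an upsampled nonnegative feature map
#'
#' `decoder_blocks` repetitions of stride-2 transposed convolution, batch
#' normalisation (running statistics at evaluation) and ReLU; each block
#' doubles the spatial size.
#'
#' @param tokens `[n_tokens, d_model]` matrix on the model's token grid.
#' @param model a [init_posenet()] model.
#' @return `[H', W', C]` array, nonnegative.
#' @export
decode <- function(tokens, model) {
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  res <- decode_node(tape, bind, tp_const(tape, tokens), model)
  mat_to_fm(res$fm$value, res$H, res$W)
}

#' Linear keypoint head
#'
#' Flattens the decoder feature map and applies the affine map `W k + b`,
#' un-standardises with the training-target moments, and reshapes to J x 3
#' millimetre coordinates.
#'
#' @param k feature-map array from [decode()].
#' @param model a [init_posenet()] model.
#' @return `n_joints x 3` matrix (mm), columns x, y, z.
#' @export
predict_keypoints <- function(k, model) {
  stopifnot(all(is.finite(k)))
  v <- matrix(as.vector(k), 1)
  z <- v %*% model$params[["head.W"]] + model$params[["head.b"]]
  z <- z * model$target_sd + model$target_mean
  out <- matrix(as.vector(z), model$cfg$n_joints, 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Predict a 3D pose from a pressure frame
#'
#' Full evaluation path: encoder, decoder (running batch-norm statistics)
#' and keypoint head. Deterministic for a given model and input.
#'
#' @param frame `H x W` pressure frame (kPa).
#' @param model a trained [init_posenet()] model.
#' @return `n_joints x 3` matrix (mm).
#' @export
predict_pose <- function(frame, model) {
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  x <- tp_const(tape, matrix(as.vector(frame / model$max_value), ncol = 1))
  enc <- encode_node(tape, bind, x, model)
  dec <- decode_node(tape, bind, enc$tok, model, training = FALSE)
  z <- head_node(tape, bind, dec$fm)$value
  z <- z * model$target_sd + model$target_mean
  out <- matrix(as.vector(z), model$cfg$n_joints, 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Train the stage-2 pose regressor
#'
#' MSE over the J x 3 standardised coordinates, Adam updates, batch-norm
#' running statistics with momentum 0.1. Inputs are frames (clean, restored
#' or noisy — the caller chooses) paired with keypoint labels.
#'
#' @param scenes list of records with `pose` and a frame under `frame`
#'   (falling back to `clean`).
#' @param cfg a [posenet_config()].
#' @param lr,epochs,batch,seed training hyperparameters.
#' @param max_value normalisation ceiling for frames (kPa).
#' @param verbose print per-epoch losses.
#' @return list with `model`, `history` tibble and `mean_pose` (the training
#'   mean pose, the constant-predictor baseline).
#' @export
train_stage2 <- function(scenes, cfg = posenet_config(), lr = 1e-3,
                         epochs = 10, batch = 8, seed = 1, max_value = 15,
                         verbose = FALSE) {
  get_frame <- function(s) if (!is.null(s$frame)) s$frame else s$clean
  f1 <- get_frame(scenes[[1]])
  model <- init_posenet(cfg, nrow(f1), ncol(f1), derive_seed(seed, "init"))
  model$max_value <- max_value
  targets <- t(vapply(scenes, function(s) as.vector(t(unclass(s$pose)[, 1:3])),
                      numeric(3 * cfg$n_joints)))
  model$target_mean <- colMeans(targets)
  model$target_sd <- pmax(apply(targets, 2, stats::sd), 1e-6)
  tstd <- sweep(sweep(targets, 2, model$target_mean), 2, model$target_sd, "/")
  n <- length(scenes)
  state <- adam_init(model$params)
  history <- numeric(epochs)
  mom <- 0.1
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "order", ep), sample.int(n))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (i in ord) {
      x <- get_frame(scenes[[i]]) / max_value
      tape <- tp_new()
      bind <- make_binder(tape, model$params)
      enc <- encode_node(tape, bind, tp_const(tape, matrix(as.vector(x), ncol = 1)),
                         model)
      dec <- decode_node(tape, bind, enc$tok, model, training = TRUE)
      pred <- head_node(tape, bind, dec$fm)
      loss <- op_mse(tape, pred, matrix(tstd[i, ], 1))
      if (!is.finite(loss$value)) {
        stop_("stage-2 training diverged (non-finite loss at epoch %d)", ep)
      }
      ep_loss <- ep_loss + loss$value
      for (k in seq_along(dec$new_stats)) {
        st <- model$bn_stats[[k]]
        model$bn_stats[[k]]$mean <- (1 - mom) * st$mean + mom * dec$new_stats[[k]]$mean
        model$bn_stats[[k]]$var <- (1 - mom) * st$var + mom * dec$new_stats[[k]]$var
      }
      g <- tp_backward(tape, loss)
      if (is.null(acc)) acc <- g else {
        for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
      }
      acc_n <- acc_n + 1L
      if (acc_n == batch || i == ord[length(ord)]) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / acc_n
        upd <- adam_step(model$params, acc, state, lr = lr)
        model$params <- upd$params
        state <- upd$state
        acc <- NULL; acc_n <- 0L
      }
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("stage2 epoch %d: loss %.6f", ep, history[ep]))
  }
  mean_pose <- matrix(model$target_mean, cfg$n_joints, 3, byrow = TRUE)
  colnames(mean_pose) <- c("x", "y", "z")
  list(model = model,
       history = tibble::tibble(epoch = seq_len(epochs), loss = history),
       mean_pose = mean_pose)
}
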