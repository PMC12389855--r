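# Dual-diffusion signal enhancement (DDSE): a small U-Net denoiser entered
# through the CDA layer, trained per step along the noisy-to-clean path,
# and a reverse loop that restores a frame from its forward-diffused state.
#
# Internally frames are normalised by the sensor ceiling so signal and mask
# share the diffusion noise scale; outputs are mapped back to kPa.

#' U-Net configuration
#'
#' @param depth number of encoder/decoder levels (spatial halvings).
#' @param base_channels channels at the top level; level l uses
#'   `base_channels * 2^(l-1)`.
#' @param cda a [cda_config()]; its `channels` must equal `base_channels`
#'   (the CDA output is the U-Net input).
#' @return object of class `unet_config`.
#' @export
unet_config <- function(depth = 3, base_channels = 32,
                        cda = cda_config(channels = base_channels)) {
  if (depth < 1) stop_("depth must be >= 1")
  if (cda$channels != base_channels) {
    stop_("cda$channels (%d) must equal base_channels (%d)",
          cda$channels, base_channels)
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels), cda = cda),
            class = "unet_config")
}

#' Initialise a DDSE model (CDA + U-Net)
#'
#' @param cfg a [unet_config()].
#' @param seed init seed.
#' @param flags ablation switches: `rmfd` (mask stream), `ca`
#'   (cross-attention fusion), `pp` (pyramidal pooling). The pressure-stream
#'   forward diffusion is always on; dropping `ca` drops `pp`.
#' @return object of class `ddse_model`.
#' @export
init_ddse <- function(cfg = unet_config(), seed = 1,
                      flags = list(rmfd = TRUE, ca = TRUE, pp = TRUE)) {
  flags <- utils::modifyList(list(rmfd = TRUE, ca = TRUE, pp = TRUE), flags)
  if (!flags$ca) flags$pp <- FALSE
  p <- init_cda_params(cfg$cda, derive_seed(seed, "cda"))
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  cin <- cfg$base_channels
  for (l in seq_len(cfg$depth)) {
    p[[sprintf("unet.enc%d.W", l)]] <- w_init(9 * cin, ch[l],
                                              derive_seed(seed, "enc", l))
    p[[sprintf("unet.enc%d.b", l)]] <- zeros_row(ch[l])
    cin <- ch[l]
  }
  p[["unet.bott.W"]] <- w_init(9 * ch[cfg$depth], ch[cfg$depth],
                               derive_seed(seed, "bott"))
  p[["unet.bott.b"]] <- zeros_row(ch[cfg$depth])
  prev <- ch[cfg$depth]
  for (l in rev(seq_len(cfg$depth))) {
    p[[sprintf("unet.dec%d.up.W", l)]] <- w_init(prev, 4 * ch[l],
                                                 derive_seed(seed, "up", l),
                                                 scale = sqrt(2 / prev))
    p[[sprintf("unet.dec%d.up.b", l)]] <- zeros_row(ch[l])
    p[[sprintf("unet.dec%d.conv.W", l)]] <- w_init(9 * 2 * ch[l], ch[l],
                                                   derive_seed(seed, "dconv", l))
    p[[sprintf("unet.dec%d.conv.b", l)]] <- zeros_row(ch[l])
    prev <- ch[l]
  }
  # zero-init head: the residual branch starts as an exact no-op, so the
  # reverse chain begins at the identity and corrections grow only where
  # the loss demands them
  p[["unet.head.W"]] <- matrix(0, ch[1], 1)
  p[["unet.head.b"]] <- zeros_row(1)
  structure(list(cfg = cfg, flags = flags, params = p, sched = NULL,
                 mask = NULL, max_pressure = NULL, residual = TRUE),
            class = "ddse_model")
}

# U-Net body on the tape: x [HW, C] at (H, W) already padded to a multiple
# of 2^depth. Returns [HW, 1].
unet_body <- function(tape, bind, x, cfg, H, W) {
  skips <- list(); dims <- list()
  cur <- x; h <- H; w <- W
  for (l in seq_len(cfg$depth)) {
    s <- op_relu(tape, layer_conv(tape, cur, bind(sprintf("unet.enc%d.W", l)),
                                  bind(sprintf("unet.enc%d.b", l)), h, w, 3))
    skips[[l]] <- s; dims[[l]] <- c(h, w)
    cur <- op_matmul(tape, tp_const(tape, pool_matrix(h, w, 2)), s)
    h <- h %/% 2L; w <- w %/% 2L
  }
  cur <- op_relu(tape, layer_conv(tape, cur, bind("unet.bott.W"),
                                  bind("unet.bott.b"), h, w, 3))
  for (l in rev(seq_len(cfg$depth))) {
    up <- layer_deconv2(tape, cur, bind(sprintf("unet.dec%d.up.W", l)),
                        bind(sprintf("unet.dec%d.up.b", l)), h, w)
    h <- dims[[l]][1]; w <- dims[[l]][2]
    cat_ <- op_concat_cols(tape, up, skips[[l]])
    cur <- op_relu(tape, layer_conv(tape, cat_,
                                    bind(sprintf("unet.dec%d.conv.W", l)),
                                    bind(sprintf("unet.dec%d.conv.b", l)),
                                    h, w, 3))
  }
  op_addvec(tape, op_matmul(tape, cur, bind("unet.head.W")),
            bind("unet.head.b"))
}

pad_to_multiple <- function(H, W, m) {
  c(ceiling(H / m) * m, ceiling(W / m) * m)
}

# one denoising application on the tape: grids (normalised) -> [HW, 1] node.
# The U-Net predicts a correction that is residual-added to the pressure
# input, so the identity map is the starting point of training.
ddse_step_node <- function(tape, bind, p_mat, m_mat, t, model, H, W) {
  cfg <- model$cfg
  fl <- model$flags
  x <- cda_forward(tape, bind, p_mat, m_mat, t, cfg$cda, H, W,
                   use_mask = fl$rmfd, use_ca = fl$ca, use_pp = fl$pp)
  tgt <- pad_to_multiple(H, W, 2^cfg$depth)
  if (tgt[1] != H || tgt[2] != W) {
    C <- cfg$cda$channels
    x <- op_gather(tape, x, pad_idx(H, W, tgt[1], tgt[2], C))
    y <- unet_body(tape, bind, x, cfg, tgt[1], tgt[2])
    y <- op_gather(tape, y, crop_idx(tgt[1], tgt[2], H, W, 1L))
  } else {
    y <- unet_body(tape, bind, x, cfg, H, W)
  }
  if (isTRUE(model$residual)) op_add(tape, y, p_mat) else y
}

#' Apply the U-Net denoiser to a CDA feature map
#'
#' Pads the spatial dimensions symmetrically with zeros to a multiple of
#' `2^depth` if necessary and crops the single-channel output back.
#'
#' @param x `[H, W, C]` array, typically from [cda()].
#' @param model a [init_ddse()] model.
#' @return `H x W` matrix.
#' @export
unet_forward <- function(x, model) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cfg <- model$cfg
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  xn <- tp_const(tape, fm_to_mat(x))
  tgt <- pad_to_multiple(H, W, 2^cfg$depth)
  if (tgt[1] != H || tgt[2] != W) {
    xn <- op_gather(tape, xn, pad_idx(H, W, tgt[1], tgt[2], dim(x)[3]))
    y <- unet_body(tape, bind, xn, cfg, tgt[1], tgt[2])
    y <- op_gather(tape, y, crop_idx(tgt[1], tgt[2], H, W, 1L))
  } else {
    y <- unet_body(tape, bind, xn, cfg, H, W)
  }
  matrix(y$value, H, W)
}

# evaluate one reverse step without gradients: normalised grids in, grid out
ddse_apply <- function(model, p_t, m_t, t) {
  H <- nrow(p_t); W <- ncol(p_t)
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  out <- ddse_step_node(tape, bind, tp_const(tape, fm_to_mat(p_t)),
                        tp_const(tape, fm_to_mat(m_t)), t, model, H, W)
  matrix(out$value, H, W)
}

#' Train the stage-1 denoiser
#'
#' Per-step supervision along the noisy-to-clean path: for each scene a
#' random step t in 1..D is drawn; the input is the forward diffusion (to
#' step t) of the interpolant `clean + (t/D) * (noisy - clean)`, conditioned
#' on the independently diffused refined mask, and the regression target
#' (MSE, Adam) is the signal-scale-(t-1) multiple of the interpolant at
#' (t-1)/D. Each reverse step thus removes exactly 1/D of the sensor noise
#' plus that step's diffusion noise, the training inputs match the reverse
#' chain's own intermediates at every step, and the final step (t = 1)
#' lands on the clean frame.
#'
#' @param scenes list of scene records with `clean` and `noisy` matrices
#'   (e.g. `make_dataset(...)$scenes`).
#' @param sched a [make_schedule()].
#' @param mask a [mask_params()] for refined-mask generation.
#' @param model a [init_ddse()] model (or NULL to initialise from `cfg`).
#' @param cfg used when `model` is NULL.
#' @param lr,epochs,batch,seed Adam learning rate, epochs, gradient
#'   accumulation batch size, training seed.
#' @param max_pressure sensor ceiling used to normalise frames.
#' @param val_scenes optional held-out scenes; restoration MSE is computed on
#'   them after training via [reverse_denoise()].
#' @param verbose print per-epoch losses.
#' @return list with `model`, `history` (tibble epoch/loss) and `val_mse`.
#' @export
train_stage1 <- function(scenes, sched, mask = mask_params(),
                         model = NULL, cfg = unet_config(),
                         lr = 3e-3, epochs = 5, batch = 2, seed = 1,
                         max_pressure = 15, val_scenes = NULL,
                         verbose = FALSE) {
  if (is.null(model)) model <- init_ddse(cfg, derive_seed(seed, "init"))
  model$sched <- sched
  model$mask <- mask
  model$max_pressure <- max_pressure
  n <- length(scenes)
  masks0 <- lapply(scenes, function(s) refine(s$noisy, mask))
  state <- adam_init(model$params)
  history <- numeric(epochs)
  ctr <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "order", ep), sample.int(n))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (i in ord) {
      ctr <- ctr + 1L
      s <- scenes[[i]]
      t <- with_seed(derive_seed(seed, "t", ctr), sample.int(sched$D, 1))
      base_in <- s$clean + (t / sched$D) * (s$noisy - s$clean)
      base_tgt <- s$clean + ((t - 1) / sched$D) * (s$noisy - s$clean)
      p_t <- diffuse_to(base_in / max_pressure, t, sched,
                        derive_seed(seed, "eps_p", ctr))
      m_t <- diffuse_to(masks0[[i]], t, sched, derive_seed(seed, "eps_m", ctr))
      target <- diffusion_signal_scale(sched, t - 1) * base_tgt / max_pressure
      tape <- tp_new()
      bind <- make_binder(tape, model$params)
      out <- ddse_step_node(tape, bind, tp_const(tape, fm_to_mat(p_t)),
                            tp_const(tape, fm_to_mat(m_t)), t, model,
                            nrow(p_t), ncol(p_t))
      loss <- op_mse(tape, out, matrix(target, length(target), 1))
      if (!is.finite(loss$value)) {
        stop_("stage-1 training diverged (non-finite loss at epoch %d)", ep)
      }
      ep_loss <- ep_loss + loss$value
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
    if (verbose) message(sprintf("stage1 epoch %d: loss %.6f", ep, history[ep]))
  }
  val_mse <- NA_real_
  if (!is.null(val_scenes) && length(val_scenes) > 0) {
    errs <- vapply(seq_along(val_scenes), function(i) {
      s <- val_scenes[[i]]
      rest <- reverse_denoise(s$noisy, sched, mask, model,
                              rng_seed = derive_seed(seed, "val", i))
      mean((rest - s$clean)^2)
    }, numeric(1))
    val_mse <- mean(errs)
  }
  list(model = model,
       history = tibble::tibble(epoch = seq_len(epochs), loss = history),
       val_mse = val_mse)
}

#' Restore a noisy pressure frame by reverse denoising
#'
#' Refines the binary mask from the raw input (t = 0), forward-diffuses the
#' input and the mask to step D with stored trajectories, then iterates the
#' denoiser from t = D down to 1, conditioning each step on the stored
#' diffused mask. The result is clipped to `[0, max_pressure]`.
#'
#' @param p_noisy `H x W` pressure frame (kPa).
#' @param sched schedule; must match the one the model was trained with
#'   (`NULL` uses the model's stored schedule; a `D = 0` degenerate schedule
#'   returns the clipped input).
#' @param mask mask parameters (`NULL`: the model's stored ones).
#' @param model a trained [init_ddse()] model.
#' @param rng_seed seed for the forward-diffusion noise.
#' @return restored `H x W` matrix.
#' @export
reverse_denoise <- function(p_noisy, sched = NULL, mask = NULL, model,
                            rng_seed = 1) {
  stopifnot(all(is.finite(p_noisy)))
  if (is.null(sched)) sched <- model$sched
  if (is.null(mask)) mask <- model$mask
  maxp <- if (is.null(model$max_pressure)) 15 else model$max_pressure
  if (!is.null(sched) && !is.null(model$sched) && sched$D != model$sched$D) {
    stop_("schedule has D = %d but the model was trained with D = %d",
          sched$D, model$sched$D)
  }
  if (is.null(sched) || sched$D == 0) return(clamp(p_noisy, 0, maxp))
  m0 <- refine(p_noisy, mask)
  traj_p <- forward_trajectory(p_noisy / maxp, sched, derive_seed(rng_seed, "p"))
  traj_m <- forward_trajectory(m0, sched, derive_seed(rng_seed, "m"))
  p_hat <- traj_p[[sched$D + 1]]
  for (t in seq(sched$D, 1)) {
    p_hat <- ddse_apply(model, p_hat, traj_m[[t + 1]], t)
  }
  clamp(p_hat * maxp, 0, maxp)
}
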