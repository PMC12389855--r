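# Contour detection and alignment (CDA) layer: atrous pyramidal pooling of
# the mask stream, fused into the pressure stream by spatially pooled
# cross-attention. Sits at the denoising U-Net's entrance and is re-applied
# at every reverse step, conditioned on the step index through a sinusoidal
# embedding added to both stems.

#' CDA layer configuration
#'
#' @param atrous_rates strictly increasing dilation rates of the 3x3 atrous
#'   branches in the pyramidal pooling block.
#' @param channels feature channels of both streams.
#' @param pool_size side of the non-overlapping average pooling applied to the
#'   mask stream before it forms attention keys/values.
#' @param n_heads attention heads; must divide `channels`.
#' @return object of class `cda_config`.
#' @export
cda_config <- function(atrous_rates = c(2, 4, 6, 8), channels = 8,
                       pool_size = 4, n_heads = 2) {
  if (any(diff(atrous_rates) <= 0) || any(atrous_rates < 1)) {
    stop_("atrous_rates must be strictly increasing positive integers")
  }
  if (channels %% n_heads != 0) stop_("channels must be divisible by n_heads")
  if (pool_size < 1) stop_("pool_size must be >= 1")
  structure(list(atrous_rates = as.integer(atrous_rates),
                 channels = as.integer(channels),
                 pool_size = as.integer(pool_size),
                 n_heads = as.integer(n_heads)),
            class = "cda_config")
}

# parameter set of a CDA layer (shared naming with the U-Net model)
init_cda_params <- function(cfg, seed) {
  C <- cfg$channels
  p <- list()
  p[["cda.stem_p.W"]] <- w_init(1, C, derive_seed(seed, "stem_p"))
  p[["cda.stem_p.b"]] <- zeros_row(C)
  p[["cda.stem_m.W"]] <- w_init(1, C, derive_seed(seed, "stem_m"))
  p[["cda.stem_m.b"]] <- zeros_row(C)
  p[["cda.temb.W"]] <- w_init(C, C, derive_seed(seed, "temb"), scale = sqrt(1 / C))
  p[["cda.temb.b"]] <- zeros_row(C)
  for (r in cfg$atrous_rates) {
    p[[sprintf("cda.pp.r%d.W", r)]] <- w_init(9 * C, C, derive_seed(seed, "pp", r))
    p[[sprintf("cda.pp.r%d.b", r)]] <- zeros_row(C)
  }
  p[["cda.pp.proj.W"]] <- w_init(length(cfg$atrous_rates) * C, C,
                                 derive_seed(seed, "ppproj"))
  p[["cda.pp.proj.b"]] <- zeros_row(C)
  for (nm in c("Wq", "Wk", "Wv")) {
    p[[paste0("cda.ca.", nm)]] <- w_init(C, C, derive_seed(seed, nm),
                                         scale = sqrt(1 / C))
  }
  # zero-init output projection: the attention residual starts silent and
  # the mask pathway only contributes once training asks for it
  p[["cda.ca.Wo"]] <- matrix(0, C, C)
  for (nm in c("bq", "bk", "bv", "bo")) p[[paste0("cda.ca.", nm)]] <- zeros_row(C)
  p
}

#' Standalone CDA model
#'
#' Initialises the layer's parameters for direct use of [pyramidal_pool()],
#' [cross_attend()] and [cda()]; inside the denoiser the same parameters live
#' in the U-Net model.
#'
#' @param cfg a [cda_config()].
#' @param seed integer init seed.
#' @return object of class `cda_model` with fields `cfg` and `params`.
#' @export
init_cda <- function(cfg = cda_config(), seed = 1) {
  structure(list(cfg = cfg, params = init_cda_params(cfg, seed)),
            class = "cda_model")
}

fm_to_mat <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])
}

mat_to_fm <- function(m, H, W) array(m, c(H, W, ncol(m)))

check_pp_size <- function(cfg, H, W) {
  need <- 2L * max(cfg$atrous_rates) + 1L
  if (H < need || W < need) {
    stop_(paste0("input %dx%d is smaller than the largest dilated receptive ",
                 "field; pyramidal pooling with rates (%s) needs at least ",
                 "%dx%d"), H, W, paste(cfg$atrous_rates, collapse = ","),
          need, need)
  }
}

# tape-level pyramidal pooling on an [HW, C] node
pp_forward <- function(tape, bind, x, cfg, H, W) {
  check_pp_size(cfg, H, W)
  branches <- lapply(cfg$atrous_rates, function(r) {
    layer_conv(tape, x, bind(sprintf("cda.pp.r%d.W", r)),
               bind(sprintf("cda.pp.r%d.b", r)), H, W, 3, dil = r)
  })
  cat_ <- branches[[1]]
  for (b in branches[-1]) cat_ <- op_concat_cols(tape, cat_, b)
  op_addvec(tape, op_matmul(tape, cat_, bind("cda.pp.proj.W")),
            bind("cda.pp.proj.b"))
}

# tape-level cross-attention: queries from the pressure stream, keys/values
# from the spatially pooled mask stream; residual-added to the query stream.
ca_forward <- function(tape, bind, q, kv, cfg, H, W, collect_attn = NULL) {
  P <- tp_const(tape, pool_matrix(H, W, cfg$pool_size))
  kv_p <- op_matmul(tape, P, kv)
  res <- mha(tape, q, kv_p, bind, "cda.ca", cfg$n_heads)
  if (!is.null(collect_attn)) collect_attn$attn <- res$attn
  op_add(tape, q, res$out)
}

stem_forward <- function(tape, bind, x, which, t, cfg) {
  s <- op_addvec(tape, op_matmul(tape, x, bind(sprintf("cda.stem_%s.W", which))),
                 bind(sprintf("cda.stem_%s.b", which)))
  emb <- tp_const(tape, sinusoidal_embedding(t, cfg$channels))
  tproj <- op_addvec(tape, op_matmul(tape, emb, bind("cda.temb.W")),
                     bind("cda.temb.b"))
  op_addvec(tape, s, tproj)
}

# full CDA on the tape; flags switch the ablation variants
cda_forward <- function(tape, bind, p_node, m_node, t, cfg, H, W,
                        use_mask = TRUE, use_ca = TRUE, use_pp = TRUE,
                        collect_attn = NULL) {
  sp <- stem_forward(tape, bind, p_node, "p", t, cfg)
  if (!use_mask || !use_ca) return(sp)
  sm <- stem_forward(tape, bind, m_node, "m", t, cfg)
  if (use_pp) sm <- pp_forward(tape, bind, sm, cfg, H, W)
  ca_forward(tape, bind, sp, sm, cfg, H, W, collect_attn)
}

#' Pyramidal pooling of a feature map
#'
#' One 3x3 atrous-convolution branch per configured rate (same padding, so
#' the spatial size is preserved), concatenated over channels and projected
#' back to `channels` by a 1x1 convolution.
#'
#' @param x feature map, `[H, W, C]` array (or `H x W` matrix lifted through
#'   the 1-channel stem convention is not applied here — `C` must equal
#'   `cfg$channels`).
#' @param model a [init_cda()] model.
#' @return `[H, W, C]` array.
#' @export
pyramidal_pool <- function(x, model) {
  m <- fm_to_mat(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (ncol(m) != model$cfg$channels) {
    stop_("x must have %d channels (got %d)", model$cfg$channels, ncol(m))
  }
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  out <- pp_forward(tape, bind, tp_const(tape, m), model$cfg, H, W)
  mat_to_fm(out$value, H, W)
}

#' Spatially pooled cross-attention between two streams
#'
#' Queries come from the pressure-stream features, keys/values from the mask
#' stream after non-overlapping average pooling by `pool_size`. Standard
#' multi-head scaled dot-product attention; the output is residual-added to
#' the query stream.
#'
#' @param query_src `[H, W, C]` array (pressure-stream features).
#' @param kv_src `[H, W, C]` array (mask-stream features), same H, W.
#' @param model a [init_cda()] model.
#' @param return_attn also return per-head attention matrices.
#' @return `[H, W, C]` array, or a list with `out` and `attn`.
#' @export
cross_attend <- function(query_src, kv_src, model, return_attn = FALSE) {
  if (!identical(dim(query_src)[1:2], dim(kv_src)[1:2])) {
    stop_("query_src and kv_src must share spatial dimensions")
  }
  H <- dim(query_src)[1]; W <- dim(query_src)[2]
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  coll <- if (return_attn) new.env() else NULL
  out <- ca_forward(tape, bind, tp_const(tape, fm_to_mat(query_src)),
                    tp_const(tape, fm_to_mat(kv_src)), model$cfg, H, W, coll)
  res <- mat_to_fm(out$value, H, W)
  if (return_attn) list(out = res, attn = coll$attn) else res
}

#' Full CDA layer on raw grids
#'
#' Lifts the pressure and mask grids through their 1x1 stems (plus the
#' sinusoidal embedding of the step index), pyramid-pools the mask stream and
#' fuses it into the pressure stream by cross-attention. This is the
#' conditioned input handed to the U-Net at every reverse step.
#'
#' @param p_t `H x W` pressure grid at step t.
#' @param m_t `H x W` (soft) mask grid at step t.
#' @param t integer step index.
#' @param model a [init_cda()] model.
#' @return `[H, W, channels]` array.
#' @export
cda <- function(p_t, m_t, t, model) {
  check_same_shape(p_t, m_t, "p_t and m_t")
  tape <- tp_new()
  bind <- make_binder(tape, model$params)
  out <- cda_forward(tape, bind, tp_const(tape, fm_to_mat(p_t)),
                     tp_const(tape, fm_to_mat(m_t)), t, model$cfg,
                     nrow(p_t), ncol(p_t))
  mat_to_fm(out$value, nrow(p_t), ncol(p_t))
}
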