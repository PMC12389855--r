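# Neural-net layers built on the autodiff tape, plus Adam and weight init.
# Index maps for convolution gathers are cached per geometry.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- make()
  .idx_cache[[key]]
}

# im2col index for a k x k convolution with dilation `dil`, "same" zero
# padding, input [H*W, Cin]. Column order: channel outer, then kernel column,
# then kernel row (row offset fastest) — the weight matrix rows follow the
# same order.
conv_idx <- function(H, W, k, dil, Cin) {
  key <- paste("conv", H, W, k, dil, Cin, sep = "_")
  cache_get(key, function() {
    r <- (k - 1L) %/% 2L
    offs <- dil * seq(-r, r)
    HW <- H * W
    i <- rep(seq_len(H), W)
    j <- rep(seq_len(W), each = H)
    cols <- vector("list", k * k * Cin)
    q <- 0L
    for (c in seq_len(Cin)) for (b in offs) for (a in offs) {
      q <- q + 1L
      ii <- i + a; jj <- j + b
      ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
      idx <- ifelse(ok, ii + (jj - 1L) * H + (c - 1L) * HW, HW * Cin + 1L)
      cols[[q]] <- idx
    }
    matrix(unlist(cols), HW, k * k * Cin)
  })
}

# scatter index for a 2 x 2, stride-2 transposed convolution: input [H*W, Cin]
# maps to output [2H*2W, Cout]. Column order matches the deconv weight layout
# [Cin, 4*Cout]: output channel outer, kernel column, kernel row.
deconv_idx <- function(H, W, Cout) {
  key <- paste("deconv", H, W, Cout, sep = "_")
  cache_get(key, function() {
    H2 <- 2L * H; W2 <- 2L * W
    i <- rep(seq_len(H), W)
    j <- rep(seq_len(W), each = H)
    cols <- vector("list", 4L * Cout)
    q <- 0L
    for (o in seq_len(Cout)) for (b in 1:2) for (a in 1:2) {
      q <- q + 1L
      oi <- 2L * (i - 1L) + a
      oj <- 2L * (j - 1L) + b
      cols[[q]] <- oi + (oj - 1L) * H2 + (o - 1L) * H2 * W2
    }
    matrix(unlist(cols), H * W, 4L * Cout)
  })
}

# dense averaging matrix for non-overlapping f x f mean pooling; trailing
# blocks may be smaller, each row averages its own block (rows sum to 1)
pool_matrix <- function(H, W, f) {
  key <- paste("pool", H, W, f, sep = "_")
  cache_get(key, function() {
    Ho <- ceiling(H / f); Wo <- ceiling(W / f)
    P <- matrix(0, Ho * Wo, H * W)
    i <- rep(seq_len(H), W)
    j <- rep(seq_len(W), each = H)
    oi <- (i - 1L) %/% f + 1L
    oj <- (j - 1L) %/% f + 1L
    P[cbind(oi + (oj - 1L) * Ho, seq_len(H * W))] <- 1
    P / rowSums(P)
  })
}

# gather index embedding an H x W frame into Ht x Wt with symmetric zero pad
pad_idx <- function(H, W, Ht, Wt, Cin) {
  key <- paste("pad", H, W, Ht, Wt, Cin, sep = "_")
  cache_get(key, function() {
    r0 <- (Ht - H) %/% 2L
    c0 <- (Wt - W) %/% 2L
    i <- rep(seq_len(Ht), Wt) - r0
    j <- rep(seq_len(Wt), each = Ht) - c0
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    base <- ifelse(ok, i + (j - 1L) * H, NA_integer_)
    out <- matrix(0L, Ht * Wt, Cin)
    for (c in seq_len(Cin)) {
      out[, c] <- ifelse(ok, base + (c - 1L) * H * W, H * W * Cin + 1L)
    }
    out
  })
}

# inverse of pad_idx: crop the centred H x W window out of Ht x Wt
crop_idx <- function(Ht, Wt, H, W, Cin) {
  key <- paste("crop", Ht, Wt, H, W, Cin, sep = "_")
  cache_get(key, function() {
    r0 <- (Ht - H) %/% 2L
    c0 <- (Wt - W) %/% 2L
    i <- rep(seq_len(H), W) + r0
    j <- rep(seq_len(W), each = H) + c0
    base <- i + (j - 1L) * Ht
    out <- matrix(0L, H * W, Cin)
    for (c in seq_len(Cin)) out[, c] <- base + (c - 1L) * Ht * Wt
    out
  })
}

layer_conv <- function(tape, x, Wn, bn, H, W, k, dil = 1) {
  Cin <- ncol(x$value)
  v <- op_gather(tape, x, conv_idx(H, W, k, dil, Cin))
  op_addvec(tape, op_matmul(tape, v, Wn), bn)
}

layer_deconv2 <- function(tape, x, Wn, bn, H, W) {
  Cout <- ncol(Wn$value) %/% 4L
  cols <- op_matmul(tape, x, Wn)
  out <- op_scatter(tape, cols, deconv_idx(H, W, Cout), 4L * H * W, Cout)
  op_addvec(tape, out, bn)
}

#' @keywords internal
sinusoidal_embedding <- function(t, d) {
  half <- d %/% 2
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  emb <- c(sin(t * freq), cos(t * freq))
  if (length(emb) < d) emb <- c(emb, 0)
  matrix(emb[seq_len(d)], 1)
}

# multi-head scaled dot-product attention; queries from `q` [nq, d], keys and
# values from `kv` [nk, d]. Returns the output node plus the per-head
# attention matrices (values), whose rows each sum to 1.
mha <- function(tape, q, kv, bind, prefix, n_heads) {
  d <- ncol(q$value)
  dh <- d %/% n_heads
  Q <- op_addvec(tape, op_matmul(tape, q, bind(paste0(prefix, ".Wq"))),
                 bind(paste0(prefix, ".bq")))
  K <- op_addvec(tape, op_matmul(tape, kv, bind(paste0(prefix, ".Wk"))),
                 bind(paste0(prefix, ".bk")))
  V <- op_addvec(tape, op_matmul(tape, kv, bind(paste0(prefix, ".Wv"))),
                 bind(paste0(prefix, ".bv")))
  outs <- vector("list", n_heads)
  attn <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    jj <- ((h - 1) * dh + 1):(h * dh)
    qh <- op_cols(tape, Q, jj)
    kh <- op_cols(tape, K, jj)
    vh <- op_cols(tape, V, jj)
    logits <- op_scale(tape, op_matmul(tape, qh, op_t(tape, kh)), 1 / sqrt(dh))
    A <- op_softmax_rows(tape, logits)
    attn[[h]] <- A$value
    outs[[h]] <- op_matmul(tape, A, vh)
  }
  cat_ <- outs[[1]]
  for (h in seq_len(n_heads)[-1]) cat_ <- op_concat_cols(tape, cat_, outs[[h]])
  out <- op_addvec(tape, op_matmul(tape, cat_, bind(paste0(prefix, ".Wo"))),
                   bind(paste0(prefix, ".bo")))
  list(out = out, attn = attn)
}

## ---- parameters ----

# binder: lazily wrap model parameters as tape nodes, one node per name
make_binder <- function(tape, params) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) {
      if (is.null(params[[name]])) stop_("unknown parameter '%s'", name)
      cache[[name]] <- tp_param(tape, params[[name]], name)
    }
    cache[[name]]
  }
}

w_init <- function(nin, nout, seed, scale = sqrt(2 / nin)) {
  with_seed(seed, matrix(rnorm(nin * nout, 0, scale), nin, nout))
}

zeros_row <- function(d) matrix(0, 1, d)
ones_row <- function(d) matrix(1, 1, d)

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
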