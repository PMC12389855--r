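# Shared fixtures: desk-scale configurations and small random inputs.
# Frames at 32x20 (training scale) and 160x96 (mask-refinement scale) stand
# in for the sensor's native 496x298 resolution.

tiny_scene_cfg <- function(seed = 11) {
  scene_config(grid_h = 16, grid_w = 8, frame_h = 32, frame_w = 20,
               spurious_blob_size = 2, seed = seed)
}

mask_scene_cfg <- function(seed = 3) {
  scene_config(frame_h = 160, frame_w = 96, seed = seed)
}

tiny_mask_params <- function() mask_params(kernel = 3, n_erosions = 1, n_dilations = 1)

tiny_unet_cfg <- function(channels = 8) {
  unet_config(depth = 2, base_channels = channels,
              cda = cda_config(channels = channels, pool_size = 2, n_heads = 2))
}

tiny_sched <- function(D = 10) make_schedule(D, 0.99995, 0.9999)

rand_frame <- function(h, w, seed = 1) {
  tactpose:::with_seed(seed, matrix(runif(h * w), h, w))
}

rand_mask <- function(h, w, p = 0.4, seed = 1) {
  tactpose:::with_seed(seed, matrix(rbinom(h * w, 1, p), h, w))
}

# finite-difference gradient of fn(params) w.r.t. selected entries of one
# parameter; the oracle for all backpropagation checks
num_grad <- function(fn, params, nm, idx, eps = 1e-5) {
  p <- params[[nm]]
  g <- numeric(length(idx))
  for (q in seq_along(idx)) {
    k <- idx[q]
    pp <- p
    pp[k] <- pp[k] + eps; params[[nm]] <- pp; fp <- fn(params)
    pp[k] <- pp[k] - 2 * eps; params[[nm]] <- pp; fm <- fn(params)
    g[q] <- (fp - fm) / (2 * eps)
  }
  params[[nm]] <- p
  g
}

# brute-force labelling of 4-connected components (independent of the
# package's label_components); returns the number of components
brute_n_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1 && !seen[i, j]) {
      n <- n + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          a <- p[1] + d[1]; b <- p[2] + d[2]
          if (a >= 1 && a <= h && b >= 1 && b <= w && mask[a, b] == 1 && !seen[a, b]) {
            seen[a, b] <- TRUE
            stack[[length(stack) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  n
}

# direct-summation dilated 3x3 correlation with zero padding; weights taken
# from the model's [9*C, C] matrix in its (channel, kcol, krow) order
brute_dilated_conv <- function(x, Wmat, bias, rate) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- ncol(Wmat)
  out <- array(0, c(H, W, Cout))
  offs <- rate * (-1:1)
  for (co in seq_len(Cout)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- bias[co]
      q <- 0
      for (c in seq_len(Cin)) for (b in offs) for (a in offs) {
        q <- q + 1
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + x[ii, jj, c] * Wmat[q, co]
        }
      }
      out[i, j, co] <- acc
    }
  }
  out
}
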