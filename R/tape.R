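# Minimal reverse-mode autodiff over matrices.
#
# Feature maps are stored as [H*W, C] matrices (column-major position index
# p = i + (j-1)*H); convolutions become gather (im2col) + matmul, transposed
# convolutions matmul + scatter, and pooling a constant-matrix product. Each
# node records its parents and a backward closure returning the parent
# gradients, so whole models differentiate mechanically. Gradients of every
# primitive are verified against finite differences in the test suite.

tp_new <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

tp_push <- function(tape, node) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node$idx <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

tp_leaf <- function(tape, value, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- list()
  node$backward <- NULL
  node$name <- name
  node$need_grad <- !is.null(name)
  node$grad <- NULL
  tp_push(tape, node)
}

tp_const <- function(tape, value) tp_leaf(tape, value, name = NULL)
tp_param <- function(tape, value, name) tp_leaf(tape, value, name = name)

tp_op <- function(tape, value, parents, backward) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$name <- NULL
  node$need_grad <- any(vapply(parents, function(p) p$need_grad, logical(1)))
  node$grad <- NULL
  tp_push(tape, node)
}

# Backpropagate from `node` (seed gradient defaults to 1 for scalars) and
# return the named list of parameter gradients.
tp_backward <- function(tape, node, seed = 1) {
  node$grad <- if (length(node$value) == 1) seed else {
    g <- node$value; g[] <- seed; g
  }
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    pg <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$need_grad || is.null(pg[[i]])) next
      p$grad <- if (is.null(p$grad)) pg[[i]] else p$grad + pg[[i]]
    }
  }
  grads <- list()
  for (k in seq_len(tape$n)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$name) && !is.null(nd$grad)) grads[[nd$name]] <- nd$grad
  }
  grads
}

## ---- primitives ----

op_add <- function(tape, a, b) {
  tp_op(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

op_sub <- function(tape, a, b) {
  tp_op(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

op_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  tp_op(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_scale <- function(tape, a, k) {
  tp_op(tape, a$value * k, list(a), function(g) list(g * k))
}

op_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  tp_op(tape, av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), t(av) %*% g))
}

op_t <- function(tape, a) {
  tp_op(tape, t(a$value), list(a), function(g) list(t(g)))
}

op_relu <- function(tape, a) {
  mask <- a$value > 0
  tp_op(tape, a$value * mask, list(a), function(g) list(g * mask))
}

# add a 1 x d row vector to every row of an n x d matrix
op_addvec <- function(tape, x, v) {
  n <- nrow(x$value)
  tp_op(tape, x$value + matrix(v$value, n, length(v$value), byrow = TRUE),
        list(x, v),
        function(g) list(g, matrix(colSums(g), 1)))
}

op_concat_cols <- function(tape, a, b) {
  na <- ncol(a$value)
  tp_op(tape, cbind(a$value, b$value), list(a, b),
        function(g) list(g[, seq_len(na), drop = FALSE],
                         g[, -seq_len(na), drop = FALSE]))
}

op_cols <- function(tape, x, jj) {
  d <- ncol(x$value)
  tp_op(tape, x$value[, jj, drop = FALSE], list(x),
        function(g) {
          out <- matrix(0, nrow(g), d)
          out[, jj] <- g
          list(out)
        })
}

op_softmax_rows <- function(tape, x) {
  v <- x$value
  m <- apply(v, 1, max)
  e <- exp(v - m)
  y <- e / rowSums(e)
  tp_op(tape, y, list(x),
        function(g) list((g - rowSums(g * y)) * y))
}

op_layernorm_rows <- function(tape, x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  va <- rowMeans((v - mu)^2)
  sd_ <- sqrt(va + eps)
  xhat <- (v - mu) / sd_
  gam <- as.vector(gamma$value)
  y <- xhat * matrix(gam, nrow(v), ncol(v), byrow = TRUE) +
    matrix(as.vector(beta$value), nrow(v), ncol(v), byrow = TRUE)
  tp_op(tape, y, list(x, gamma, beta), function(g) {
    gy <- g * matrix(gam, nrow(g), ncol(g), byrow = TRUE)
    dx <- (gy - rowMeans(gy) - xhat * rowMeans(gy * xhat)) / sd_
    list(dx, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

# batch norm over rows (stats per column/channel); `stats` = list(mean, var)
# switches to fixed (running) statistics, as used at evaluation time.
op_batchnorm_cols <- function(tape, x, gamma, beta, eps = 1e-5, stats = NULL) {
  v <- x$value
  n <- nrow(v)
  gam <- as.vector(gamma$value)
  bet <- as.vector(beta$value)
  if (!is.null(stats)) {
    sd_ <- sqrt(stats$var + eps)
    xhat <- (v - matrix(stats$mean, n, ncol(v), byrow = TRUE)) /
      matrix(sd_, n, ncol(v), byrow = TRUE)
    y <- xhat * matrix(gam, n, ncol(v), byrow = TRUE) +
      matrix(bet, n, ncol(v), byrow = TRUE)
    return(tp_op(tape, y, list(x, gamma, beta), function(g) {
      list(g * matrix(gam / sd_, n, ncol(g), byrow = TRUE),
           matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
    }))
  }
  mu <- colMeans(v)
  va <- colMeans(sweep(v, 2, mu)^2)
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(v, 2, mu), 2, sd_, "/")
  y <- sweep(xhat, 2, gam, "*")
  y <- sweep(y, 2, bet, "+")
  tp_op(tape, y, list(x, gamma, beta), function(g) {
    gxh <- sweep(g, 2, gam, "*")
    dx <- sweep(gxh, 2, colMeans(gxh)) -
      xhat * matrix(colMeans(gxh * xhat), n, ncol(g), byrow = TRUE)
    dx <- sweep(dx, 2, sd_, "/")
    list(dx, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

# gather: value[p, q] = xvec[idx[p, q]] where xvec = c(x$value, 0) and the
# sentinel index length(x)+1 represents zero padding.
op_gather <- function(tape, x, idx) {
  nx <- length(x$value)
  xv <- c(as.vector(x$value), 0)
  val <- matrix(xv[idx], nrow(idx), ncol(idx))
  xdim <- dim(x$value)
  tp_op(tape, val, list(x), function(g) {
    acc <- rowsum(as.vector(g), as.vector(idx))
    full <- numeric(nx + 1)
    full[as.integer(rownames(acc))] <- acc
    list(matrix(full[seq_len(nx)], xdim[1], xdim[2]))
  })
}

# scatter-add: out (out_rows x out_cols) with out[idx[p, q]] += cols[p, q];
# idx entries of 0 are dropped. Inverse of gather.
op_scatter <- function(tape, cols, idx, out_rows, out_cols) {
  nout <- out_rows * out_cols
  keep <- idx > 0
  acc <- rowsum(as.vector(cols$value)[keep], as.vector(idx)[keep])
  full <- numeric(nout)
  full[as.integer(rownames(acc))] <- acc
  val <- matrix(full, out_rows, out_cols)
  tp_op(tape, val, list(cols), function(g) {
    gv <- c(as.vector(g), 0)
    idx2 <- ifelse(idx > 0, idx, nout + 1)
    list(matrix(gv[idx2], nrow(idx), ncol(idx)))
  })
}

op_mse <- function(tape, pred, target) {
  tv <- if (is.numeric(target)) target else target$value
  d <- pred$value - tv
  n <- length(d)
  tp_op(tape, sum(d^2) / n, list(pred),
        function(g) list(g * 2 * d / n))
}
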