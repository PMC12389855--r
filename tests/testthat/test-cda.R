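# CDA layer: brute-force oracles for the atrous pyramid and the pooled
# cross-attention (brute_dilated_conv in helper-fixtures.R), plus its
# structural invariants.

test_that("single atrous branch equals brute-force dilated correlation", {
  cfg <- cda_config(atrous_rates = 2, channels = 2, pool_size = 2, n_heads = 1)
  model <- init_cda(cfg, seed = 4)
  x <- array(tactpose:::with_seed(3, rnorm(9 * 9 * 2)), c(9, 9, 2))
  got <- pyramidal_pool(x, model)
  br <- brute_dilated_conv(x, model$params[["cda.pp.r2.W"]],
                           model$params[["cda.pp.r2.b"]], 2)
  # single rate: output is the branch projected by the 1x1 conv
  proj <- tactpose:::fm_to_mat(br) %*% model$params[["cda.pp.proj.W"]]
  proj <- proj + matrix(model$params[["cda.pp.proj.b"]], nrow(proj), 2,
                        byrow = TRUE)
  expect_lt(max(abs(got - tactpose:::mat_to_fm(proj, 9, 9))), 1e-5)
})

test_that("full pyramid matches the explicit-loop oracle on a 16x16 input", {
  cfg <- cda_config(atrous_rates = c(2, 4), channels = 4, pool_size = 4,
                    n_heads = 2)
  model <- init_cda(cfg, seed = 9)
  x <- array(tactpose:::with_seed(11, rnorm(16 * 16 * 4)), c(16, 16, 4))
  got <- pyramidal_pool(x, model)
  brs <- lapply(c(2, 4), function(r) {
    brute_dilated_conv(x, model$params[[sprintf("cda.pp.r%d.W", r)]],
                       model$params[[sprintf("cda.pp.r%d.b", r)]], r)
  })
  cat_ <- cbind(tactpose:::fm_to_mat(brs[[1]]), tactpose:::fm_to_mat(brs[[2]]))
  proj <- cat_ %*% model$params[["cda.pp.proj.W"]]
  proj <- proj + matrix(model$params[["cda.pp.proj.b"]], nrow(proj), 4,
                        byrow = TRUE)
  expect_lt(max(abs(got - tactpose:::mat_to_fm(proj, 16, 16))), 1e-5)
})

test_that("pyramidal pooling refuses inputs below the receptive field and zero maps to zero", {
  model <- init_cda(cda_config(channels = 2, n_heads = 1), seed = 1)
  x <- array(0, c(10, 10, 2))
  expect_error(pyramidal_pool(x, model), "receptive field")
  m2 <- init_cda(cda_config(atrous_rates = c(2, 4), channels = 2, n_heads = 1),
                 seed = 1)
  z <- pyramidal_pool(array(0, c(12, 12, 2)), m2)
  expect_equal(max(abs(z)), 0) # zero biases: zero input -> zero output
})

test_that("cross-attention matches the explicit softmax(QK/sqrt(d))V oracle", {
  cfg <- cda_config(atrous_rates = 2, channels = 4, pool_size = 2, n_heads = 2)
  model <- init_cda(cfg, seed = 6)
  model$params[["cda.ca.Wo"]] <- tactpose:::w_init(4, 4, 99, scale = 0.5)
  q <- array(tactpose:::with_seed(21, rnorm(4 * 4 * 4)), c(4, 4, 4))
  kv <- array(tactpose:::with_seed(22, rnorm(4 * 4 * 4)), c(4, 4, 4))
  got <- cross_attend(q, kv, model, return_attn = TRUE)
  # oracle: explicit loops
  p <- model$params
  qm <- tactpose:::fm_to_mat(q); km <- tactpose:::fm_to_mat(kv)
  pooled <- tactpose:::pool_matrix(4, 4, 2) %*% km
  addb <- function(m, b) m + matrix(b, nrow(m), ncol(b), byrow = TRUE)
  Q <- addb(qm %*% p[["cda.ca.Wq"]], p[["cda.ca.bq"]])
  K <- addb(pooled %*% p[["cda.ca.Wk"]], p[["cda.ca.bk"]])
  V <- addb(pooled %*% p[["cda.ca.Wv"]], p[["cda.ca.bv"]])
  heads <- list(1:2, 3:4)
  outm <- NULL
  for (h in 1:2) {
    jj <- heads[[h]]
    A <- matrix(0, nrow(Q), nrow(K))
    for (i in seq_len(nrow(Q))) {
      lg <- numeric(nrow(K))
      for (k in seq_len(nrow(K))) lg[k] <- sum(Q[i, jj] * K[k, jj]) / sqrt(2)
      e <- exp(lg - max(lg))
      A[i, ] <- e / sum(e)
    }
    expect_lt(max(abs(A - got$attn[[h]])), 1e-6)
    expect_equal(rowSums(got$attn[[h]]), rep(1, nrow(A)), tolerance = 1e-6)
    outm <- cbind(outm, A %*% V[, jj, drop = FALSE])
  }
  final <- addb(outm %*% p[["cda.ca.Wo"]], p[["cda.ca.bo"]]) + qm
  expect_lt(max(abs(tactpose:::fm_to_mat(got$out) - final)), 1e-5)
})

test_that("attention degenerates correctly for constant and single-token keys", {
  cfg <- cda_config(atrous_rates = 2, channels = 4, pool_size = 100, n_heads = 1)
  model <- init_cda(cfg, seed = 8)
  model$params[["cda.ca.Wo"]] <- tactpose:::w_init(4, 4, 98, scale = 0.5)
  q <- array(tactpose:::with_seed(31, rnorm(6 * 5 * 4)), c(6, 5, 4))
  kv <- array(tactpose:::with_seed(32, rnorm(6 * 5 * 4)), c(6, 5, 4))
  # pool_size covers the whole map: a single kv token, softmax weight 1
  res <- cross_attend(q, kv, model, return_attn = TRUE)
  expect_equal(unname(res$attn[[1]]), matrix(1, 30, 1), tolerance = 1e-12)
  p <- model$params
  addb <- function(m, b) m + matrix(b, nrow(m), ncol(b), byrow = TRUE)
  tok <- matrix(colMeans(tactpose:::fm_to_mat(kv)), 1)
  v <- addb(addb(tok %*% p[["cda.ca.Wv"]], p[["cda.ca.bv"]]) %*% p[["cda.ca.Wo"]],
            p[["cda.ca.bo"]])
  expected <- tactpose:::fm_to_mat(q) + matrix(v, 30, 4, byrow = TRUE)
  expect_lt(max(abs(tactpose:::fm_to_mat(res$out) - expected)), 1e-8)
  # constant kv: every output token is value-mean + residual, by uniformity
  cfg2 <- cda_config(atrous_rates = 2, channels = 4, pool_size = 2, n_heads = 1)
  m2 <- init_cda(cfg2, seed = 9)
  m2$params[["cda.ca.Wo"]] <- tactpose:::w_init(4, 4, 96, scale = 0.5)
  kvc <- array(1, c(6, 6, 4))
  q2 <- array(tactpose:::with_seed(33, rnorm(6 * 6 * 4)), c(6, 6, 4))
  r2 <- cross_attend(q2, kvc, m2, return_attn = TRUE)
  expect_lt(max(abs(r2$attn[[1]] - 1 / ncol(r2$attn[[1]]))), 1e-12)
})

test_that("attention is invariant to key-token permutation and local in queries", {
  cfg <- cda_config(atrous_rates = 2, channels = 4, pool_size = 1, n_heads = 2)
  model <- init_cda(cfg, seed = 12)
  model$params[["cda.ca.Wo"]] <- tactpose:::w_init(4, 4, 97, scale = 0.5)
  q <- array(tactpose:::with_seed(41, rnorm(4 * 4 * 4)), c(4, 4, 4))
  kv <- tactpose:::with_seed(42, matrix(rnorm(16 * 4), 16, 4))
  out1 <- cross_attend(q, tactpose:::mat_to_fm(kv, 4, 4), model)
  perm <- tactpose:::with_seed(43, sample.int(16))
  out2 <- cross_attend(q, tactpose:::mat_to_fm(kv[perm, ], 4, 4), model)
  expect_lt(max(abs(out1 - out2)), 1e-10)
  # query locality: changing one query pixel changes only that row
  q2 <- q; q2[2, 3, ] <- q2[2, 3, ] + 1
  o1 <- tactpose:::fm_to_mat(cross_attend(q, tactpose:::mat_to_fm(kv, 4, 4), model))
  o2 <- tactpose:::fm_to_mat(cross_attend(q2, tactpose:::mat_to_fm(kv, 4, 4), model))
  changed <- which(rowSums(abs(o1 - o2)) > 1e-12)
  expect_equal(changed, 2 + (3 - 1) * 4)
})

test_that("full CDA contract: shapes, and zero mask leaves only the value shift", {
  cfg <- cda_config(atrous_rates = c(2, 4), channels = 6, pool_size = 4,
                    n_heads = 2)
  model <- init_cda(cfg, seed = 14)
  p_t <- rand_frame(20, 12, 51)
  m_t <- rand_mask(20, 12, 0.4, 52)
  out <- cda(p_t, m_t, 3, model)
  expect_equal(dim(out), c(20, 12, 6))
  expect_true(all(is.finite(out)))
  # zero mask + zero-bias network (time-embedding path zeroed): the mask
  # stream carries exact zeros through PP and attention values, so the
  # output is the pressure stem alone (residual path)
  m0 <- model
  m0$params[["cda.temb.W"]][] <- 0
  z <- cda(p_t, matrix(0, 20, 12), 3, m0)
  tape <- tactpose:::tp_new()
  bind <- tactpose:::make_binder(tape, m0$params)
  sp <- tactpose:::stem_forward(tape, bind,
                                tactpose:::tp_const(tape, tactpose:::fm_to_mat(p_t)),
                                "p", 3, cfg)
  expect_lt(max(abs(tactpose:::fm_to_mat(z) - sp$value)), 1e-10)
})
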