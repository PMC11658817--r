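test_that("attention scores and softmax behave on hand-constructed cases", {
  # zero attention vectors -> every score sigmoid(0) = 0.5
  g <- graph_from_neighbors(list(c(2L), c(1L)))
  H <- matrix(c(1, 2, 3, 4), 2, 2)
  W <- diag(2)
  e <- attention_scores(H, W, vs = c(0, 0), vr = c(0, 0), g)
  expect_equal(e[1, 1], 0.5)
  expect_equal(e[1, 2], 0.5)

  # single node with only a self-loop: one score in (0,1), alpha = 1
  g1 <- graph_from_neighbors(list(integer(0)))
  e1 <- attention_scores(matrix(1.5, 1, 1), matrix(1, 1, 1), 0.3, -0.2, g1)
  expect_gt(e1[1, 1], 0)
  expect_lt(e1[1, 1], 1)
  a1 <- normalize_attention(e1, g1)
  expect_equal(a1[1, 1], 1)

  # equal scores over a 3-member neighborhood -> uniform 1/3
  g3 <- graph_from_neighbors(list(c(2L, 3L), c(1L), c(1L)))
  e3 <- attention_scores(matrix(0, 3, 2), diag(2), c(1, 1), c(1, 1), g3)
  a3 <- normalize_attention(e3, g3)
  expect_equal(unname(a3[1, ]), rep(1 / 3, 3))

  # scores (0, ln 2) -> softmax (1/3, 2/3); set scores directly
  es <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                             x = c(0, log(2), 0, 0), dims = c(2, 2))
  a2 <- normalize_attention(es, graph_from_neighbors(list(c(2L), c(1L))))
  expect_equal(unname(a2[1, ]), c(1 / 3, 2 / 3))

  expect_error(attention_scores(matrix(NaN, 2, 2), W, c(0, 0), c(0, 0), g),
               "non-finite")
})

test_that("encoder and decoder layers match the scalar double-loop oracle", {
  set.seed(7)
  for (n in c(4, 8, 10)) {
    coords <- random_graph_coords(n, seed = n)
    g <- build_sng(coords, rad_cutoff = 2.0)
    nbrs <- g$neighbors
    d_in <- 5; d_out <- 3
    H <- matrix(rnorm(n * d_in), n, d_in)
    W <- matrix(rnorm(d_out * d_in) / 2, d_out, d_in)
    vs <- rnorm(d_out); vr <- rnorm(d_out)
    for (act in c("elu", "relu", "identity")) {
      orc <- oracle_attention_layer(H, W, vs, vr, nbrs, act)
      out <- encoder_layer(H, list(W = W, vs = vs, vr = vr), g, act)
      expect_equal(out, orc$H, tolerance = 1e-10)
      e <- attention_scores(H, W, vs, vr, g, act)
      a <- normalize_attention(e, g)
      expect_equal(as.matrix(a), orc$alpha, tolerance = 1e-10,
                   ignore_attr = TRUE)
      # decoder propagates by the same rule with its own parameters
      outd <- decoder_layer(H, list(W = W, vs = vs, vr = vr), g, act)
      expect_equal(outd, orc$H, tolerance = 1e-10)
    }
  }
})

test_that("degenerate layer configurations reduce to closed forms", {
  # self-loops only, identity weights and activation: h_i = W h_i = h_i
  g <- graph_from_neighbors(list(integer(0), integer(0)))
  H <- matrix(c(1, -2, 0.5, 3), 2, 2)
  out <- encoder_layer(H, list(W = diag(2), vs = c(1, 2), vr = c(-1, 0)), g,
                       "identity")
  expect_equal(out, H)
  outd <- decoder_layer(H, list(W = diag(2), vs = c(0, 0), vr = c(0, 0)), g,
                        "identity")
  expect_equal(outd, H)

  # identity W and sigma, uniform attention over {i, j}: mean of the two rows
  g2 <- graph_from_neighbors(list(c(2L), c(1L)))
  out2 <- encoder_layer(H, list(W = diag(2), vs = c(0, 0), vr = c(0, 0)), g2,
                        "identity")
  expect_equal(out2, (H + H[c(2, 1), ]) / 2)
})

test_that("attention rows always sum to one, refined or not", {
  fx <- tiny_fixture(seed = 3)
  cfg <- gaae_config(layer_dims = c(8, 3), epochs = 15, learning_rate = 1e-3,
                     seed = 3)
  fit <- gaae_train(fx$ds, fx$g, cfg)
  expect_lt(fit$attn_rowsum_dev, 1e-6)
  for (P in c(fit$attention$enc, fit$attention$dec))
    expect_equal(unname(Matrix::rowSums(P)), rep(1, fx$g$n_spots),
                 tolerance = 1e-6)

  a <- fit$attention$enc[[1]]
  expect_equal(as.matrix(refine_attention(a, fx$g, 0)), as.matrix(a),
               tolerance = 1e-12)
  u <- refine_attention(a, fx$g, 1)
  deg <- vapply(fx$g$neighbors, length, 1L) + 1
  expect_equal(unname(u[1, u[1, ] > 0]), rep(1 / deg[1], deg[1]))
  half <- refine_attention(a, fx$g, 0.5)
  expect_equal(as.matrix(half), (as.matrix(a) + as.matrix(u)) / 2,
               tolerance = 1e-12)
  expect_equal(unname(Matrix::rowSums(half)), rep(1, fx$g$n_spots),
               tolerance = 1e-12)
})

test_that("loss reduces to the feature term when lambda is zero", {
  fx <- tiny_fixture(seed = 4)
  X <- fx$ds$expr
  set.seed(4)
  Xh <- X + rnorm(length(X)) / 10
  L <- matrix(rnorm(nrow(X) * 3), ncol = 3)
  expect_equal(gaae_loss(X, X, L, fx$g, 0), 0)
  expect_equal(gaae_loss(X, Xh, L, fx$g, 0),
               sum(sqrt(rowSums((X - Xh)^2))))

  # single undirected edge, orthogonal embeddings, perfect reconstruction:
  # loss = -lambda * 2 * log(1/2) = 2 lambda log 2
  g2 <- graph_from_neighbors(list(c(2L), c(1L)))
  L2 <- rbind(c(1, 0), c(0, 1))
  X2 <- matrix(1, 2, 2)
  lam <- 0.7
  expect_equal(gaae_loss(X2, X2, L2, g2, lam), 2 * lam * log(2))
})

test_that("training is reproducible, monotone in trend, and epoch-0 safe", {
  fx <- tiny_fixture(seed = 5)
  cfg <- gaae_config(layer_dims = c(8, 3), epochs = 25, learning_rate = 1e-3,
                     seed = 11)
  f1 <- gaae_train(fx$ds, fx$g, cfg)
  f2 <- gaae_train(fx$ds, fx$g, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$latent, f2$latent)

  expect_lt(f1$loss_history[length(f1$loss_history)], f1$loss_history[1])

  f0 <- gaae_train(fx$ds, fx$g, gaae_config(layer_dims = c(8, 3), epochs = 0,
                                            seed = 11))
  expect_length(f0$loss_history, 1)
  expect_true(is.finite(f0$loss_history))
})

test_that("an identity-capable configuration drives the loss near zero", {
  # lambda = 0, self-loops-only graph, one full-width identity-activation
  # layer: the auto-encoder can represent the identity map
  set.seed(9)
  X <- matrix(rnorm(50 * 20), 50, 20)
  g <- graph_from_neighbors(replicate(50, integer(0), simplify = FALSE),
                            coords = cbind(seq_len(50) * 10, 0))
  cfg <- gaae_config(layer_dims = 20, lambda_struct = 0, activation = "identity",
                     epochs = 400, learning_rate = 2e-2, weight_decay = 0,
                     gradient_clip = 1e6, seed = 2)
  fit <- gaae_train(X, g, cfg)
  lh <- fit$loss_history
  expect_lt(lh[length(lh)], 1e-2 * lh[1])
})

test_that("embeddings are permutation-equivariant", {
  fx <- tiny_fixture(seed = 6)
  cfg <- gaae_config(layer_dims = c(6, 2), epochs = 10, learning_rate = 1e-3,
                     seed = 8)
  f <- gaae_train(fx$ds, fx$g, cfg)
  set.seed(1)
  perm <- sample(fx$g$n_spots)
  ds_p <- fx$ds
  ds_p$expr <- ds_p$expr[perm, ]
  ds_p$counts <- ds_p$counts[perm, ]
  ds_p$coords <- ds_p$coords[perm, ]
  ds_p$spot_ids <- ds_p$spot_ids[perm]
  g_p <- build_sng(ds_p$coords, rad_cutoff = fx$g$rad_cutoff)
  f_p <- gaae_train(ds_p, g_p, cfg)
  expect_equal(f_p$latent, f$latent[perm, ], tolerance = 1e-8)
})

test_that("tied decoder weights stay the encoder transpose through training", {
  fx <- tiny_fixture(seed = 7)
  cfg <- gaae_config(layer_dims = c(6, 2), epochs = 8, learning_rate = 1e-3,
                     tie_weights = TRUE, seed = 3)
  f <- gaae_train(fx$ds, fx$g, cfg)
  for (k in seq_len(f$model$L))
    expect_equal(f$model$dec[[k]]$W, t(f$model$enc[[k]]$W), tolerance = 1e-12)
})
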