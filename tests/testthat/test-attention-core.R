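test_that("layer norm centres and scales rows and matches the loop oracle", {
  w <- norm_weights(4)
  # constant row collapses to zero (variance resolved by epsilon)
  expect_equal(layer_norm(matrix(5, 2, 4), w), matrix(0, 2, 4))
  # invariance to per-row constant shifts
  set.seed(0)
  x <- matrix(rnorm(12), 3, 4)
  shift <- matrix(rep(c(5, -2, 7), 4), 3, 4)
  expect_equal(layer_norm(x, w), layer_norm(x + shift, w), tolerance = 1e-8)
  # random affine weights vs element-wise oracle
  w$gain <- runif(4, 0.5, 2)
  w$shift <- rnorm(4)
  expect_lt(max(abs(layer_norm(x, w) -
                    oracle_layer_norm(x, w$gain, w$shift))), 1e-6)
  expect_error(layer_norm(x, norm_weights(5)), "dim")
})

test_that("dd layer equals the closed form (Wx)*x + Wx", {
  w <- linear_weights(2, 2, bias = FALSE, init = "identity")
  expect_equal(dd_layer(matrix(0, 3, 2), w), matrix(0, 3, 2))
  # identity weights: x*x + x
  expect_equal(dd_layer(matrix(c(2, -1), 1, 2), w), matrix(c(6, 0), 1, 2))
  set.seed(1)
  x <- matrix(rnorm(6), 2, 3)
  w <- linear_weights(3, 3)
  expect_lt(max(abs(dd_layer(x, w) - oracle_dd(x, w$W, w$b))), 1e-6)
  expect_error(dd_layer(x, linear_weights(3, 4)), "square")
})

test_that("scaled dot attention normalizes weights and matches brute force", {
  # single token: softmax of a scalar is 1, output equals V
  q <- matrix(rnorm(4), 1, 4)
  v <- matrix(rnorm(4), 1, 4)
  expect_equal(scaled_dot_attention(q, q, v, 4), v)
  # identical keys give uniform weights -> column means of V
  set.seed(2)
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rep(rnorm(4), each = 5), 5, 4)
  V <- matrix(rnorm(20), 5, 4)
  out <- scaled_dot_attention(Q, K, V, 4)
  expect_equal(out, matrix(colMeans(V), 3, 4, byrow = TRUE), tolerance = 1e-8)
  # random case vs double-loop oracle
  K2 <- matrix(rnorm(12), 3, 4); V2 <- matrix(rnorm(12), 3, 4)
  expect_lt(max(abs(scaled_dot_attention(Q, K2, V2, 4) -
                    oracle_sdp(Q, K2, V2, 4))), 1e-6)
  expect_error(scaled_dot_attention(Q, K2, V2, 0), "positive")
})

test_that("multi-head attention composes per-head attention and projection", {
  set.seed(3)
  d <- 6
  Q <- matrix(rnorm(18), 3, d); K <- matrix(rnorm(18), 3, d)
  V <- matrix(rnorm(18), 3, d)
  # h = 1 with identity output projection reduces to plain attention
  w1 <- list(out_proj = linear_weights(d, d, bias = FALSE, init = "identity"))
  p1 <- attention_params(1, d, 0, 0)
  expect_equal(multi_head_attention(Q, K, V, w1, p1),
               scaled_dot_attention(Q, K, V, d), tolerance = 1e-10)
  # zero inputs, zero biases -> zero output
  w <- mha_weights(d)
  p <- attention_params(3, 2, 0, 0)
  expect_equal(multi_head_attention(matrix(0, 2, d), matrix(0, 2, d),
                                    matrix(0, 2, d), w, p),
               matrix(0, 2, d))
  # permuting queries permutes output rows identically
  perm <- c(3, 1, 2)
  out <- multi_head_attention(Q, K, V, w, p)
  expect_equal(multi_head_attention(Q[perm, ], K, V, w, p), out[perm, ],
               tolerance = 1e-10)
  expect_error(multi_head_attention(Q, K, V, w, attention_params(4, 2, 0, 0)),
               "width")
})

test_that("mlp block and activation block follow their definitions", {
  d <- 2; dm <- 3
  w <- mlp_weights(d, dm)
  expect_equal(mlp_block(matrix(0, 2, d), w), matrix(0, 2, d))
  set.seed(3)
  x <- matrix(rnorm(8), 4, 2)
  ref <- oracle_linear(oracle_gelu(oracle_linear(
    oracle_layer_norm(x, w$norm$gain, w$norm$shift), w$w1$W, w$w1$b)),
    w$w2$W, w$w2$b)
  expect_lt(max(abs(mlp_block(x, w) - ref)), 1e-6)
  # ViT-B block parameter arithmetic (incl. its layer norm)
  pl <- cptseg:::plan_df(cptseg:::vit_branch_plan("b", 768, 3072, 196, TRUE))
  mlp_rows <- grepl("mlp", pl$component)
  expect_equal(sum(pl$params_w[mlp_rows] + pl$params_b[mlp_rows]),
               768 * 3072 + 3072 + 3072 * 768 + 768 + 2 * 768)
  # activation block: GELU(LN(x)), no linear map
  nw <- norm_weights(8)
  expect_equal(activation_block(matrix(3, 2, 8), nw), matrix(0, 2, 8))
  set.seed(4)
  y <- matrix(rnorm(32), 4, 8)
  expect_lt(max(abs(activation_block(y, nw) -
                    oracle_gelu(oracle_layer_norm(y, nw$gain, nw$shift)))),
            1e-6)
})

test_that("serial and parallel ViT layers compose their sub-blocks", {
  d <- 8; h <- 2; dm <- 16
  p <- attention_params(h, d / h, 0, 0)
  set.seed(5)
  w <- vit_branch_weights(d, h, dm)
  x <- matrix(rnorm(3 * d), 3, d)
  # manual composition of the residual sub-blocks
  a <- layer_norm(x, w$ln1)
  att <- multi_head_attention(a %*% w$wq$W + rep(w$wq$b, each = 3),
                              a %*% w$wk$W + rep(w$wk$b, each = 3),
                              a %*% w$wv$W + rep(w$wv$b, each = 3),
                              w$attn, p)
  x1 <- x + att
  ref <- x1 + mlp_block(x1, w$mlp)
  expect_equal(serial_vit_layer(x, w, p), ref, tolerance = 1e-10)
  # zeroed residual branches give the identity map
  w0 <- w
  w0$attn$out_proj$W[] <- 0; w0$attn$out_proj$b[] <- 0
  w0$mlp$w2$W[] <- 0; w0$mlp$w2$b[] <- 0
  expect_equal(serial_vit_layer(x, w0, p), x)
  # parallel layer with one branch zeroed equals the serial layer
  set.seed(6)
  wb <- vit_branch_weights(d, h, dm)
  wb$attn$out_proj$W[] <- 0; wb$attn$out_proj$b[] <- 0
  wb$mlp$w2$W[] <- 0; wb$mlp$w2$b[] <- 0
  expect_equal(parallel_vit_layer(x, list(w, wb), p),
               serial_vit_layer(x, w, p), tolerance = 1e-10)
  # three branches vs explicit branch-sum oracle
  set.seed(7)
  ws <- lapply(1:3, function(i) vit_branch_weights(d, h, dm))
  x1 <- x
  for (b in 1:3) {
    a <- layer_norm(x, ws[[b]]$ln1)
    x1 <- x1 + multi_head_attention(
      a %*% ws[[b]]$wq$W + rep(ws[[b]]$wq$b, each = 3),
      a %*% ws[[b]]$wk$W + rep(ws[[b]]$wk$b, each = 3),
      a %*% ws[[b]]$wv$W + rep(ws[[b]]$wv$b, each = 3), ws[[b]]$attn, p)
  }
  ref <- x1
  for (b in 1:3) ref <- ref + mlp_block(x1, ws[[b]]$mlp)
  expect_equal(parallel_vit_layer(x, ws, p), ref, tolerance = 1e-10)
  expect_error(parallel_vit_layer(x, list(w), p), "B >= 2")
})

test_that("attention softmax rows sum to one and eval mode is deterministic", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:6, 1); d <- sample(c(4, 8), 1)
    Q <- matrix(rnorm(n * d), n, d); K <- matrix(rnorm(n * d), n, d)
    A <- cptseg:::softmax_rows(tcrossprod(Q, K) / sqrt(d))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  }
  w <- mha_weights(8)
  p <- attention_params(2, 4, 0.3, 0.3)
  x <- matrix(rnorm(16), 2, 8)
  # dropout active only in training mode
  expect_identical(multi_head_attention(x, x, x, w, p, train = FALSE),
                   multi_head_attention(x, x, x, w, p, train = FALSE))
  set.seed(9)
  a <- multi_head_attention(x, x, x, w, p, train = TRUE)
  set.seed(9)
  b <- multi_head_attention(x, x, x, w, p, train = TRUE)
  expect_identical(a, b)
})
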