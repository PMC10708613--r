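p8 <- attention_params(2, 4, 0, 0)

test_that("branch projection applies the branch norm then Q/K/V maps", {
  d <- 8
  set.seed(10)
  bw <- cpt_branch_weights(d, n_dd = 1)
  # constant rows: LN gives zeros, so Q/K/V are the broadcast biases
  x <- matrix(2, 3, d)
  pr <- branch_project(x, bw)
  expect_equal(pr$Q, matrix(bw$wq$b, 3, d, byrow = TRUE))
  expect_equal(pr$V, matrix(bw$wv$b, 3, d, byrow = TRUE))
  # per-row constant shift invariance (inherited from the norm)
  set.seed(11)
  x <- matrix(rnorm(3 * d), 3, d)
  pr1 <- branch_project(x, bw)
  pr2 <- branch_project(x + matrix(rep(c(1, -4, 2), d), 3, d), bw)
  expect_equal(pr1$Q, pr2$Q, tolerance = 1e-7)
  # composition oracle
  xn <- oracle_layer_norm(x, bw$ln$gain, bw$ln$shift)
  expect_lt(max(abs(pr1$K - oracle_linear(xn, bw$wk$W, bw$wk$b))), 1e-6)
})

test_that("dd stack depth 0/1/2 behaves as identity / gate / double gate", {
  d <- 6
  set.seed(12)
  bw <- cpt_branch_weights(d, n_dd = 2)
  Q <- matrix(rnorm(12), 2, d); K <- matrix(rnorm(12), 2, d)
  V <- matrix(rnorm(12), 2, d)
  s0 <- apply_dd_stack(Q, K, V, bw$dd, n_dd = 0)
  expect_identical(s0$Q, Q)
  s1 <- apply_dd_stack(matrix(0, 2, d), K, V, bw$dd, n_dd = 1)
  expect_equal(s1$Q, matrix(0, 2, d))
  s2 <- apply_dd_stack(Q, K, V, bw$dd, n_dd = 2)
  ref <- oracle_dd(oracle_dd(Q, bw$dd[[1]]$q$W, bw$dd[[1]]$q$b),
                   bw$dd[[2]]$q$W, bw$dd[[2]]$q$b)
  expect_lt(max(abs(s2$Q - ref)), 1e-6)
  expect_error(apply_dd_stack(Q, K, V, bw$dd, n_dd = 3), "0, 1 or 2")
})

test_that("fusion sums branches with re-normalized queries and keys", {
  d <- 8
  set.seed(13)
  w <- cpt_layer_weights(d, 1, 0, 16)
  A <- matrix(rnorm(24), 3, d); B <- matrix(rnorm(24), 3, d)
  Z <- matrix(0, 3, d)
  # zero right branch: left queries are just re-normalized
  f <- fuse_inputs(A, A, A, Z, Z, Z, w$fuse)
  expect_equal(f$Ql, layer_norm(A, w$fuse$ln_ql), tolerance = 1e-10)
  expect_equal(f$Vl, A)
  # equal branches: LN of the doubled matrix
  f2 <- fuse_inputs(A, A, A, A, A, A, w$fuse)
  expect_equal(f2$Ql, layer_norm(2 * A, w$fuse$ln_ql), tolerance = 1e-10)
  # values fuse without a norm; right queries/keys keep their own norm
  f3 <- fuse_inputs(A, A, A, B, B, B, w$fuse)
  expect_equal(f3$Vl, A + B)
  expect_equal(f3$Qr, layer_norm(B, w$fuse$ln_qr), tolerance = 1e-10)
})

test_that("left and right attentions follow the cross-coupling", {
  d <- 8
  set.seed(14)
  w <- cpt_layer_weights(d, 1, 0, 16)
  Q <- matrix(rnorm(8), 1, d); V <- matrix(rnorm(8), 1, d)
  # single token: attention output is the projected value row
  ol <- left_attention(Q, Q, V, w$left$attn, p8)
  expect_equal(ol, V %*% w$left$attn$out_proj$W +
                 rep(w$left$attn$out_proj$b, each = 1), tolerance = 1e-10)
  # zero left output: right attention reduces to plain self-attention
  Vr <- matrix(rnorm(8), 1, d)
  orr <- right_attention(Q, Q, Vr, matrix(0, 1, d), w$right$attn, p8)
  expect_equal(orr, Vr %*% w$right$attn$out_proj$W +
                 rep(w$right$attn$out_proj$b, each = 1), tolerance = 1e-10)
  # left output shifts the right values additively
  or2 <- right_attention(Q, Q, Vr, ol, w$right$attn, p8)
  expect_equal(or2, (Vr + ol) %*% w$right$attn$out_proj$W +
                 rep(w$right$attn$out_proj$b, each = 1), tolerance = 1e-10)
})

test_that("C-PMHSA equals the chained oracle on 100 seeded instances", {
  d <- 8
  for (i in 1:100) {
    set.seed(100 + i)
    n <- sample(2:5, 1)
    n_dd <- sample(0:2, 1)
    w <- cpt_layer_weights(d, n_dd, 0, 16)
    z <- matrix(rnorm(n * d), n, d)
    expect_lt(max(abs(cpmhsa_forward(z, w, p8) - oracle_cpmhsa(z, w, 2))),
              1e-6)
  }
})

test_that("zeroed output projections silence the block", {
  d <- 8
  set.seed(15)
  w <- cpt_layer_weights(d, 1, 0, 16)
  w$left$attn$out_proj$W[] <- 0; w$left$attn$out_proj$b[] <- 0
  w$right$attn$out_proj$W[] <- 0; w$right$attn$out_proj$b[] <- 0
  z <- matrix(rnorm(24), 3, d)
  expect_equal(cpmhsa_forward(z, w, p8), matrix(0, 3, d))
  # the layer then reduces to GELU(LN(z))
  expect_equal(cpt_layer_forward(z, w, p8),
               activation_block(z, w$act), tolerance = 1e-10)
})

test_that("cpt layer applies residual then activation or parallel MLPs", {
  d <- 8
  set.seed(16)
  z <- matrix(rnorm(32), 4, d)
  w0 <- cpt_layer_weights(d, 1, 0, 16)
  z1 <- cpmhsa_forward(z, w0, p8) + z
  expect_equal(cpt_layer_forward(z, w0, p8), activation_block(z1, w0$act),
               tolerance = 1e-10)
  # 2-MLP ablation: parallel feed-forward blocks replace the bare block
  w2 <- cpt_layer_weights(d, 1, 2, 16)
  z1b <- cpmhsa_forward(z, w2, p8) + z
  ref <- z1b + mlp_block(z1b, w2$mlp[[1]]) + mlp_block(z1b, w2$mlp[[2]])
  expect_equal(cpt_layer_forward(z, w2, p8), ref, tolerance = 1e-10)
  # stacking preserves shape; 2-layer stack equals sequential application
  out <- cpt_layer_forward(cpt_layer_forward(z, w0, p8), w2, p8)
  expect_equal(dim(out), dim(z))
})

test_that("cross-branch information flows in both directions", {
  d <- 8
  set.seed(17)
  w <- cpt_layer_weights(d, 1, 0, 16)
  z <- matrix(rnorm(24), 3, d)
  base <- cpmhsa_forward(z, w, p8)
  # perturbing only left-branch value weights changes the right branch's
  # own attention output, via V'_r = V_r + O_left
  c1 <- cptseg:::cpmhsa_fwd(z, w, p8)
  w2 <- w
  w2$left$wv$W[1, 2] <- w$left$wv$W[1, 2] + 0.05
  c2 <- cptseg:::cpmhsa_fwd(z, w2, p8)
  expect_gt(max(abs(c2$cache$mr$out - c1$cache$mr$out)), 1e-8)
  # perturbing only right-branch projections changes the left attention
  # output through the fusion sums
  w3 <- w
  w3$right$wq$W[2, 3] <- w$right$wq$W[2, 3] + 0.05
  c3 <- cptseg:::cpmhsa_fwd(z, w3, p8)
  expect_gt(max(abs(c3$cache$ml$out - c1$cache$ml$out)), 1e-8)
  expect_gt(max(abs(cpmhsa_forward(z, w3, p8) - base)), 1e-8)
  # evaluation mode is bitwise reproducible
  expect_identical(cpmhsa_forward(z, w, p8), cpmhsa_forward(z, w, p8))
})

test_that("the B>2 generalization reduces to summed cross-pairs", {
  d <- 8
  set.seed(18)
  w <- cpt_multi_layer_weights(d, branches = 4, n_dd = 1)
  z <- matrix(rnorm(24), 3, d)
  ref <- z + cpmhsa_forward(z, w$pairs[[1]], p8) +
    cpmhsa_forward(z, w$pairs[[2]], p8)
  expect_equal(cptseg:::cpt_multi_layer_fwd(z, w, p8)$out,
               activation_block(ref, w$act), tolerance = 1e-10)
})
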