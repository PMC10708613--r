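# Independent brute-force oracles: explicit element-wise loops, no shared
# code with the package's vectorized implementations.

oracle_layer_norm <- function(x, gain, shift, eps = 1e-6) {
  out <- x
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    mu <- sum(row) / length(row)
    v <- sum((row - mu)^2) / length(row)
    for (j in seq_len(ncol(x))) {
      out[i, j] <- gain[j] * (x[i, j] - mu) / sqrt(v + eps) + shift[j]
    }
  }
  out
}

oracle_linear <- function(x, W, b = NULL) {
  out <- matrix(0, nrow(x), ncol(W))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(W))) {
      s <- 0
      for (k in seq_len(ncol(x))) s <- s + x[i, k] * W[k, j]
      out[i, j] <- s + if (is.null(b)) 0 else b[j]
    }
  }
  out
}

oracle_dd <- function(x, W, b = NULL) {
  h <- oracle_linear(x, W, b)
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      out[i, j] <- h[i, j] * x[i, j] + h[i, j]
    }
  }
  out
}

oracle_softmax_row <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

oracle_sdp <- function(Q, K, V, d_k) {
  n <- nrow(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    scores <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    }
    a <- oracle_softmax_row(scores)
    for (c in seq_len(ncol(V))) out[i, c] <- sum(a * V[, c])
  }
  out
}

oracle_mha <- function(Q, K, V, h, W_out, b_out = NULL) {
  d <- ncol(Q)
  dk <- d %/% h
  concat <- matrix(0, nrow(Q), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    concat[, cols] <- oracle_sdp(Q[, cols, drop = FALSE],
                                 K[, cols, drop = FALSE],
                                 V[, cols, drop = FALSE], dk)
  }
  oracle_linear(concat, W_out, b_out)
}

oracle_gelu <- function(x) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  0.5 * x * (1 + erf(x / sqrt(2)))
}

# chained C-PMHSA oracle built from the oracles above, following the
# two-branch dataflow step by step
oracle_cpmhsa <- function(z, w, h) {
  branch <- function(bw) {
    xn <- oracle_layer_norm(z, bw$ln$gain, bw$ln$shift, bw$ln$eps)
    Q <- oracle_linear(xn, bw$wq$W, bw$wq$b)
    K <- oracle_linear(xn, bw$wk$W, bw$wk$b)
    V <- oracle_linear(xn, bw$wv$W, bw$wv$b)
    for (dd in bw$dd) {
      Q <- oracle_dd(Q, dd$q$W, dd$q$b)
      K <- oracle_dd(K, dd$k$W, dd$k$b)
      V <- oracle_dd(V, dd$v$W, dd$v$b)
    }
    list(Q = Q, K = K, V = V)
  }
  L <- branch(w$left)
  R <- branch(w$right)
  Ql <- oracle_layer_norm(L$Q + R$Q, w$fuse$ln_ql$gain, w$fuse$ln_ql$shift,
                          w$fuse$ln_ql$eps)
  Kl <- oracle_layer_norm(L$K + R$K, w$fuse$ln_kl$gain, w$fuse$ln_kl$shift,
                          w$fuse$ln_kl$eps)
  Vl <- L$V + R$V
  Qr <- oracle_layer_norm(R$Q, w$fuse$ln_qr$gain, w$fuse$ln_qr$shift,
                          w$fuse$ln_qr$eps)
  Kr <- oracle_layer_norm(R$K, w$fuse$ln_kr$gain, w$fuse$ln_kr$shift,
                          w$fuse$ln_kr$eps)
  O_left <- oracle_mha(Ql, Kl, Vl, h, w$left$attn$out_proj$W,
                       w$left$attn$out_proj$b)
  O_right <- oracle_mha(Qr, Kr, R$V + O_left, h, w$right$attn$out_proj$W,
                        w$right$attn$out_proj$b)
  O_left + O_right
}

# all-pairs directed 95th-percentile surface distance oracle
oracle_hd95 <- function(pred, truth, spacing) {
  coords <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    for (j in seq_len(ncol(idx))) idx[, j] <- idx[, j] * spacing[j]
    idx
  }
  a <- coords(pred)
  b <- coords(truth)
  directed <- function(x, y) {
    d <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y))) {
        best <- min(best, sqrt(sum((x[i, ] - y[j, ])^2)))
      }
      d[i] <- best
    }
    stats::quantile(d, 0.95, names = FALSE)
  }
  max(directed(a, b), directed(b, a))
}

# small random token matrix under a fixed seed
rand_tokens <- function(n, d, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * d), n, d)
}

# reduced-width model + single phantom volume shared by training tests
tiny_cpt_config <- function(depth = 1L, branches = 2L, width = 0.25,
                            dropout = 0) {
  cpt_config("cpt", image_size = 64L, depth = depth, branches = branches,
             width_factor = width, dropout = dropout)
}
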