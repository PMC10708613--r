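## Transformer primitives shared by every network variant: layer norm, the
## dendrite-net (DD) gate, scaled dot-product and multi-head attention, the
## feed-forward MLP block, the bare LN+GELU activation block, and serial /
## parallel pre-norm ViT layers.
##
## Public functions operate on a plain numeric matrix of N tokens x d
## channels and are forward-only; the *_fwd / *_bwd internals carry caches
## for the training path.

check_tokens <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", name)
  if (any(!is.finite(x))) stopf("%s contains non-finite entries", name)
  invisible(x)
}

#' Layer normalization over channels
#'
#' Normalizes each token (row) to zero mean and unit variance across its
#' `d` channels, then applies the learned per-channel affine
#' `gain * xhat + shift`.
#'
#' @param x numeric matrix, N tokens x d channels.
#' @param w weights from [norm_weights()].
#' @return matrix of the same shape as `x`.
#' @export
layer_norm <- function(x, w) {
  check_tokens(x)
  ln_fwd(x, w)$out
}

#' Dendrite-net (DD) layer
#'
#' A Hadamard gate with a linear residual: `(W x) * x + W x`, applied
#' row-wise, where `*` is the element-wise product and the same square
#' mapping `W` appears in both terms.  The gate sharpens self-correlated
#' features while the additive term preserves the linear response.
#'
#' @param x numeric matrix, N x d.
#' @param w square [linear_weights()] mapping d to d.
#' @return matrix of the same shape as `x`.
#' @export
dd_layer <- function(x, w) {
  check_tokens(x)
  dd_fwd(x, w)$out
}

dd_fwd <- function(x, w) {
  if (nrow(w$W) != ncol(w$W)) stopf("DD layer requires a square mapping")
  if (ncol(x) != nrow(w$W)) stopf("DD weight dim %d != input dim %d",
                                  nrow(w$W), ncol(x))
  lf <- linear_fwd(x, w)
  h <- lf$out
  list(out = h * x + h, cache = list(h = h, lf = lf, x = x))
}

dd_bwd <- function(dout, cache) {
  dh <- dout * (cache$x + 1)
  lb <- linear_bwd(dh, cache$lf$cache)
  list(dx = dout * cache$h + lb$dx, dW = lb$dW, db = lb$db)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with optional dropout on the attention
#' weights in training mode.  Rows of the weight matrix sum to one.
#'
#' @param Q,K,V token matrices; `Q` and `K` share channel count, `K` and
#'   `V` share token count.
#' @param d_k scaling dimension (usually `ncol(K)`).
#' @param softmax_dropout dropout rate on the attention weights.
#' @param train logical; dropout is only active when `TRUE`.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K),
                                 softmax_dropout = 0, train = FALSE) {
  sdp_fwd(Q, K, V, d_k, softmax_dropout, train)$out
}

sdp_fwd <- function(Q, K, V, d_k, softmax_dropout = 0, train = FALSE) {
  if (d_k <= 0) stopf("d_k must be positive")
  if (ncol(Q) != ncol(K)) stopf("Q and K channel counts differ")
  if (nrow(K) != nrow(V)) stopf("K and V token counts differ")
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(d_k))
  dr <- dropout_fwd(A, softmax_dropout, train)
  out <- dr$out %*% V
  list(out = out,
       cache = list(Q = Q, K = K, V = V, d_k = d_k, A = A, dr = dr))
}

sdp_bwd <- function(dout, cache) {
  A2 <- if (is.null(cache$dr$cache)) cache$A else cache$dr$out
  dA2 <- tcrossprod(dout, cache$V)
  dV <- crossprod(A2, dout)
  dA <- dropout_bwd(dA2, cache$dr$cache)
  dZ <- softmax_rows_bwd(dA, cache$A) / sqrt(cache$d_k)
  list(dQ = dZ %*% cache$K, dK = crossprod(dZ, cache$Q), dV = dV)
}

#' Multi-head attention weights
#'
#' Per-head query/key/value maps are realized as the column blocks of the
#' upstream projections (the standard packed layout), so this constructor
#' only owns the output projection.
#'
#' @param d model width.
#' @param bias include biases.
#' @export
mha_weights <- function(d, bias = TRUE) {
  list(out_proj = linear_weights(d, d, bias = bias))
}

#' Multi-head attention
#'
#' Splits `Q`, `K`, `V` into `h` contiguous channel blocks of width `d_k`,
#' runs scaled dot-product attention independently per head, concatenates
#' the head outputs and applies the output projection, followed by output
#' dropout in training mode.
#'
#' @param Q,K,V token matrices of width `h * d_k`.
#' @param w weights from [mha_weights()].
#' @param p hyper-parameters from [attention_params()].
#' @param train logical; enables the two dropout sites.
#' @export
multi_head_attention <- function(Q, K, V, w, p, train = FALSE) {
  mha_fwd(Q, K, V, w, p, train)$out
}

mha_fwd <- function(Q, K, V, w, p, train = FALSE) {
  d <- ncol(Q)
  h <- p$n_heads
  if (d != h * p$head_dim) {
    stopf("model width %d != n_heads (%d) x head_dim (%d)", d, h, p$head_dim)
  }
  heads <- vector("list", h)
  concat <- matrix(0, nrow(Q), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * p$head_dim + 1L):(i * p$head_dim)
    heads[[i]] <- sdp_fwd(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                          V[, cols, drop = FALSE], p$head_dim,
                          p$softmax_dropout, train)
    concat[, cols] <- heads[[i]]$out
  }
  pr <- linear_fwd(concat, w$out_proj)
  dr <- dropout_fwd(pr$out, p$output_dropout, train)
  list(out = dr$out,
       cache = list(heads = heads, pr = pr, dr = dr, p = p, d = d))
}

mha_bwd <- function(dout, cache) {
  p <- cache$p
  dproj <- dropout_bwd(dout, cache$dr$cache)
  lb <- linear_bwd(dproj, cache$pr$cache)
  dQ <- matrix(0, nrow(lb$dx), cache$d)
  dK <- matrix(0, nrow(cache$heads[[1L]]$cache$K), cache$d)
  dV <- dK
  for (i in seq_len(p$n_heads)) {
    cols <- ((i - 1L) * p$head_dim + 1L):(i * p$head_dim)
    sb <- sdp_bwd(lb$dx[, cols, drop = FALSE], cache$heads[[i]]$cache)
    dQ[, cols] <- sb$dQ
    dK[, cols] <- sb$dK
    dV[, cols] <- sb$dV
  }
  list(dQ = dQ, dK = dK, dV = dV,
       dout_proj = list(dW = lb$dW, db = lb$db))
}

## ---- MLP block --------------------------------------------------------

#' Feed-forward MLP block weights (LN -> expand -> GELU -> contract)
#' @param d model width; @param d_mlp hidden width; @param bias biases.
#' @export
mlp_weights <- function(d, d_mlp, bias = TRUE) {
  list(norm = norm_weights(d),
       w1 = linear_weights(d, d_mlp, bias = bias),
       w2 = linear_weights(d_mlp, d, bias = bias))
}

#' Transformer MLP block
#'
#' `LN -> linear d->d_mlp -> GELU -> linear d_mlp->d`.  Used by the serial
#' and parallel ViT layers and by the MLP-count ablations of the C-PT
#' block; the canonical C-PT block replaces it with [activation_block()].
#'
#' @param x token matrix; @param w weights from [mlp_weights()].
#' @export
mlp_block <- function(x, w) {
  check_tokens(x)
  mlp_fwd(x, w)$out
}

mlp_fwd <- function(x, w) {
  if (ncol(w$w1$W) != nrow(w$w2$W)) stopf("MLP inner dims disagree")
  nf <- ln_fwd(x, w$norm)
  l1 <- linear_fwd(nf$out, w$w1)
  gf <- gelu_fwd(l1$out)
  l2 <- linear_fwd(gf$out, w$w2)
  list(out = l2$out, cache = list(nf = nf, l1 = l1, gf = gf, l2 = l2))
}

mlp_bwd <- function(dout, cache) {
  b2 <- linear_bwd(dout, cache$l2$cache)
  dg <- gelu_bwd(b2$dx, cache$gf$cache)
  b1 <- linear_bwd(dg, cache$l1$cache)
  bn <- ln_bwd(b1$dx, cache$nf$cache)
  list(dx = bn$dx,
       grads = list(norm = list(dgain = bn$dgain, dshift = bn$dshift),
                    w1 = list(dW = b1$dW, db = b1$db),
                    w2 = list(dW = b2$dW, db = b2$db)))
}

## ---- activation block -------------------------------------------------

#' Activation-function block
#'
#' The C-PT replacement for the feed-forward network: `GELU(LN(x))` with no
#' learned linear map and (as defined) no residual around it.  Its only
#' parameters are the 2d layer-norm affine terms.
#'
#' @param x token matrix; @param w weights from [norm_weights()].
#' @param residual add `x` back (off by default, matching the block as
#'   defined).
#' @export
activation_block <- function(x, w, residual = FALSE) {
  check_tokens(x)
  act_fwd(x, w, residual)$out
}

act_fwd <- function(x, w, residual = FALSE) {
  nf <- ln_fwd(x, w)
  gf <- gelu_fwd(nf$out)
  list(out = if (residual) x + gf$out else gf$out,
       cache = list(nf = nf, gf = gf, residual = residual))
}

act_bwd <- function(dout, cache) {
  dg <- gelu_bwd(dout, cache$gf$cache)
  bn <- ln_bwd(dg, cache$nf$cache)
  dx <- bn$dx
  if (cache$residual) dx <- dx + dout
  list(dx = dx, dgain = bn$dgain, dshift = bn$dshift)
}

## ---- serial / parallel ViT layers -------------------------------------

#' Weights for one ViT branch (attention + MLP sub-blocks)
#'
#' @param d model width; @param h heads; @param d_mlp MLP hidden width.
#' @param bias include biases.
#' @export
vit_branch_weights <- function(d = 768L, h = 12L, d_mlp = 3072L, bias = TRUE) {
  list(ln1 = norm_weights(d),
       wq = linear_weights(d, d, bias = bias),
       wk = linear_weights(d, d, bias = bias),
       wv = linear_weights(d, d, bias = bias),
       attn = mha_weights(d, bias = bias),
       mlp = mlp_weights(d, d_mlp, bias = bias))
}

#' Serial (standard pre-norm) ViT layer
#'
#' `x + MHSA(LN(x))` followed by `+ MLP(LN(.))` — the sequential
#' transformer layer used by the TransUNet-style baseline.
#'
#' @param x token matrix; @param w weights from [vit_branch_weights()].
#' @param p attention params; @param train enables dropout.
#' @export
serial_vit_layer <- function(x, w, p, train = FALSE) {
  check_tokens(x)
  vit_layer_fwd(x, list(w), p, train)$out
}

#' Parallel ViT layer
#'
#' `B >= 2` independent branches evaluated on a shared input and summed:
#' `x' = x + sum_b MHSA_b(LN_b(x))`, then `x' + sum_b MLP_b(LN_b(x'))`.
#' Rearranging a serial stack of depth `L*B` into `L` layers of `B`
#' branches leaves the total parameter count unchanged.
#'
#' @param x token matrix; @param ws list of `B` branch weight sets.
#' @param p attention params; @param train enables dropout.
#' @export
parallel_vit_layer <- function(x, ws, p, train = FALSE) {
  check_tokens(x)
  if (length(ws) < 2L) stopf("parallel ViT layer needs B >= 2 branches")
  vit_layer_fwd(x, ws, p, train)$out
}

## Shared forward for serial (1 branch) and parallel (B branches).
vit_layer_fwd <- function(x, ws, p, train = FALSE) {
  att <- vector("list", length(ws))
  x1 <- x
  for (b in seq_along(ws)) {
    w <- ws[[b]]
    nf <- ln_fwd(x, w$ln1)
    q <- linear_fwd(nf$out, w$wq)
    k <- linear_fwd(nf$out, w$wk)
    v <- linear_fwd(nf$out, w$wv)
    mh <- mha_fwd(q$out, k$out, v$out, w$attn, p, train)
    att[[b]] <- list(nf = nf, q = q, k = k, v = v, mh = mh)
    x1 <- x1 + mh$out
  }
  mlps <- vector("list", length(ws))
  out <- x1
  for (b in seq_along(ws)) {
    mf <- mlp_fwd(x1, ws[[b]]$mlp)
    mlps[[b]] <- mf
    out <- out + mf$out
  }
  list(out = out, cache = list(att = att, mlps = mlps, p = p))
}

vit_layer_bwd <- function(dout, cache) {
  B <- length(cache$att)
  grads <- vector("list", B)
  dx1 <- dout
  for (b in seq_len(B)) {
    mb <- mlp_bwd(dout, cache$mlps[[b]]$cache)
    dx1 <- dx1 + mb$dx
    grads[[b]] <- list(mlp = mb$grads)
  }
  dx <- dx1
  for (b in seq_len(B)) {
    a <- cache$att[[b]]
    mh <- mha_bwd(dx1, a$mh$cache)
    bq <- linear_bwd(mh$dQ, a$q$cache)
    bk <- linear_bwd(mh$dK, a$k$cache)
    bv <- linear_bwd(mh$dV, a$v$cache)
    bn <- ln_bwd(bq$dx + bk$dx + bv$dx, a$nf$cache)
    dx <- dx + bn$dx
    grads[[b]]$ln1 <- list(dgain = bn$dgain, dshift = bn$dshift)
    grads[[b]]$wq <- list(dW = bq$dW, db = bq$db)
    grads[[b]]$wk <- list(dW = bk$dW, db = bk$db)
    grads[[b]]$wv <- list(dW = bv$dW, db = bv$db)
    grads[[b]]$attn <- list(out_proj = mh$dout_proj)
  }
  list(dx = dx, grads = grads)
}
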