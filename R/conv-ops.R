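## 2D convolutional primitives on (H, W, C) arrays, built on im2col +
## BLAS matrix products, each with a hand-written backward pass.

.im2col_memo <- new.env(parent = emptyenv())

## Column index matrix mapping (output position, kernel element) to linear
## indices of the zero-padded input array.  Memoized per geometry.
im2col_idx <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  hit <- .im2col_memo[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)            # output row, fast
  oj <- rep(seq_len(Wo), each = Ho)
  base_i <- (oi - 1L) * stride                  # top-left of each patch
  base_j <- (oj - 1L) * stride
  ki <- rep(seq_len(kh), times = kw)            # kernel row fast, col slow
  kj <- rep(seq_len(kw), each = kh)
  ## rows: output positions; cols: (ki, kj) pairs then channels
  ii <- outer(base_i, ki, "+")                  # (HoWo) x (kh kw)
  jj <- outer(base_j, kj, "+")
  lin_hw <- ii + (jj - 1L) * Hp                 # within one channel plane
  idx <- matrix(0L, Ho * Wo, kh * kw * C)
  for (c in seq_len(C)) {
    idx[, ((c - 1L) * kh * kw + 1L):(c * kh * kw)] <- lin_hw + (c - 1L) * Hp * Wp
  }
  ## precomputed scatter structure for the backward col2im: a stable
  ## ordering of the index vector plus group boundaries, so gradients can
  ## be accumulated with one cumsum instead of a per-call rowsum
  v <- as.vector(idx)
  ord <- order(v)
  sv <- v[ord]
  ends <- c(which(diff(sv) > 0L), length(sv))
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              scatter_ord = ord, scatter_ends = ends,
              scatter_targets = sv[ends])
  .im2col_memo[[key]] <- out
  out
}

## segmented sum of dcol entries into the padded input layout
col2im_scatter <- function(dcol, g, C) {
  s <- cumsum(dcol[g$scatter_ord])
  sums <- diff(c(0, s[g$scatter_ends]))
  dxp <- numeric(g$Hp * g$Wp * C)
  dxp[g$scatter_targets] <- sums
  dxp
}

pad_input <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
  xp[(pad + 1L):(pad + d[1L]), (pad + 1L):(pad + d[2L]), ] <- x
  xp
}

#' Convolution weights
#' @param kh,kw kernel size; @param c_in,c_out channels; @param bias logical.
#' @return list with `W` (a `(kh*kw*c_in) x c_out` matrix carrying its
#'   kernel geometry as attributes) and `b`.
#' @export
conv_weights <- function(kh, kw, c_in, c_out, bias = FALSE) {
  n_in <- kh * kw * c_in
  ## He-style fan-in scaling keeps deep conv stacks trainable from scratch
  W <- matrix(stats::rnorm(n_in * c_out, sd = sqrt(2 / n_in)), n_in, c_out)
  attr(W, "kernel") <- c(kh = kh, kw = kw, c_in = c_in, c_out = c_out)
  list(W = W, b = if (bias) numeric(c_out) else NULL)
}

conv2d_fwd <- function(x, w, stride = 1L, pad = 0L) {
  k <- attr(w$W, "kernel")
  d <- dim(x)
  if (d[3L] != k[["c_in"]]) {
    stopf("conv input channels %d != %d", d[3L], k[["c_in"]])
  }
  g <- im2col_idx(d[1L], d[2L], d[3L], k[["kh"]], k[["kw"]], stride, pad)
  xp <- pad_input(x, pad)
  col <- matrix(xp[g$idx], nrow(g$idx), ncol(g$idx))
  out <- col %*% w$W
  if (!is.null(w$b)) out <- sweep(out, 2L, w$b, "+")
  list(out = array(out, c(g$Ho, g$Wo, k[["c_out"]])),
       cache = list(col = col, g = g, w = w, dims = d, stride = stride,
                    pad = pad))
}

conv2d_bwd <- function(dout, cache) {
  k <- attr(cache$w$W, "kernel")
  dmat <- matrix(dout, cache$g$Ho * cache$g$Wo, k[["c_out"]])
  dW <- crossprod(cache$col, dmat)
  attr(dW, "kernel") <- k
  db <- if (is.null(cache$w$b)) NULL else colSums(dmat)
  dcol <- tcrossprod(dmat, cache$w$W)
  ## scatter-add columns back into the padded input
  g <- cache$g
  dxp <- array(col2im_scatter(dcol, g, cache$dims[3L]),
               c(g$Hp, g$Wp, cache$dims[3L]))
  p <- cache$pad
  dx <- if (p > 0L) {
    dxp[(p + 1L):(p + cache$dims[1L]), (p + 1L):(p + cache$dims[2L]), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

## ---- group norm -------------------------------------------------------

group_norm_weights <- function(channels, groups = norm_groups(channels),
                               eps = 1e-5) {
  list(gain = rep(1, channels), shift = numeric(channels),
       groups = groups, eps = eps)
}

gn_fwd <- function(x, w) {
  d <- dim(x)
  C <- d[3L]; G <- w$groups; m <- C %/% G
  xm <- matrix(x, d[1L] * d[2L], C)
  xhat <- xm
  inv <- numeric(G); mu <- numeric(G)
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * m + 1L):(g * m)
    v <- xm[, cols]
    mu[g] <- mean(v)
    vv <- mean((v - mu[g])^2)
    inv[g] <- 1 / sqrt(vv + w$eps)
    xhat[, cols] <- (v - mu[g]) * inv[g]
  }
  out <- sweep(sweep(xhat, 2L, w$gain, "*"), 2L, w$shift, "+")
  list(out = array(out, d),
       cache = list(xhat = xhat, inv = inv, w = w, dims = d))
}

gn_bwd <- function(dout, cache) {
  w <- cache$w
  d <- cache$dims
  C <- d[3L]; G <- w$groups; m <- C %/% G
  dm <- matrix(dout, d[1L] * d[2L], C)
  dgain <- colSums(dm * cache$xhat)
  dshift <- colSums(dm)
  dxhat <- sweep(dm, 2L, w$gain, "*")
  dx <- dxhat
  n <- d[1L] * d[2L] * m
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * m + 1L):(g * m)
    dh <- dxhat[, cols]
    xh <- cache$xhat[, cols]
    dx[, cols] <- cache$inv[g] * (dh - mean(dh) - xh * mean(dh * xh))
  }
  list(dx = array(dx, d), dgain = dgain, dshift = dshift)
}

## ---- relu -------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

## ---- max pooling ------------------------------------------------------

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  g <- im2col_idx(d[1L], d[2L], d[3L], k, k, stride, pad)
  xp <- pad_input(x, pad, value = -Inf)
  col <- matrix(xp[g$idx], nrow(g$idx), ncol(g$idx))
  npos <- nrow(col); kk <- k * k; C <- d[3L]
  out <- matrix(-Inf, npos, C)
  arg <- matrix(1L, npos, C)                    # winning kernel slot
  for (s in seq_len(kk)) {
    slice <- col[, s + kk * (seq_len(C) - 1L), drop = FALSE]
    better <- slice > out
    out[better] <- slice[better]
    arg[better] <- s
  }
  list(out = array(out, c(g$Ho, g$Wo, C)),
       cache = list(g = g, arg = arg, dims = d, k = k, pad = pad))
}

maxpool_bwd <- function(dout, cache) {
  g <- cache$g; d <- cache$dims
  kk <- cache$k^2; C <- d[3L]
  npos <- nrow(cache$arg)
  dm <- matrix(dout, npos, C)
  ## linear index (into padded array) of each winner
  colpick <- cache$arg + kk * matrix(rep(seq_len(C) - 1L, each = npos), npos, C)
  win <- g$idx[cbind(rep(seq_len(npos), C), as.vector(colpick))]
  agg <- rowsum(as.vector(dm), group = win)
  dxp <- numeric(g$Hp * g$Wp * C)
  dxp[as.integer(rownames(agg))] <- agg
  dxp <- array(dxp, c(g$Hp, g$Wp, C))
  p <- cache$pad
  if (p > 0L) {
    dxp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , drop = FALSE]
  } else dxp
}

## ---- bilinear x2 upsampling ------------------------------------------

.upmat_memo <- new.env(parent = emptyenv())

## Interpolation matrix (2n x n), half-pixel-centre convention.
bilinear_mat <- function(n) {
  key <- as.character(n)
  hit <- .upmat_memo[[key]]
  if (!is.null(hit)) return(hit)
  A <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    src <- (i - 0.5) / 2 - 0.5                  # 0-based source coordinate
    lo <- floor(src)
    frac <- src - lo
    i0 <- min(max(lo, 0), n - 1)
    i1 <- min(max(lo + 1, 0), n - 1)
    A[i, i0 + 1L] <- A[i, i0 + 1L] + (1 - frac)
    A[i, i1 + 1L] <- A[i, i1 + 1L] + frac
  }
  .upmat_memo[[key]] <- A
  A
}

apply_axes <- function(x, A, B) {
  d <- dim(x)
  y1 <- A %*% matrix(x, d[1L], d[2L] * d[3L])            # rows
  y1 <- array(y1, c(nrow(A), d[2L], d[3L]))
  y2 <- B %*% matrix(aperm(y1, c(2L, 1L, 3L)), d[2L], nrow(A) * d[3L])
  aperm(array(y2, c(nrow(B), nrow(A), d[3L])), c(2L, 1L, 3L))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  A <- bilinear_mat(d[1L]); B <- bilinear_mat(d[2L])
  list(out = apply_axes(x, A, B), cache = list(A = A, B = B))
}

upsample2_bwd <- function(dout, cache) {
  apply_axes(dout, t(cache$A), t(cache$B))
}
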