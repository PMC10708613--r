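## Dense primitives on token matrices (N tokens x d channels), each with a
## hand-written backward pass.  Forward functions return list(out, cache);
## backward functions take (grad_out, cache) and return the input gradient
## plus parameter gradients.  Weight layout: W is d_in x d_out so that
## forward is a single BLAS call  x %*% W.

## ---- constructors -----------------------------------------------------

#' Linear-layer weights
#'
#' @param d_in,d_out input/output channel counts.
#' @param bias include a bias vector (default `TRUE`).
#' @param init `"trunc_normal"` (sd 0.02), `"zero"`, or `"identity"`
#'   (requires `d_in == d_out`).
#' @return list with elements `W` (`d_in x d_out`) and `b` (length `d_out`
#'   or `NULL`).
#' @export
linear_weights <- function(d_in, d_out, bias = TRUE, init = "trunc_normal") {
  W <- switch(init,
    trunc_normal = matrix(trunc_normal(d_in * d_out), d_in, d_out),
    zero = matrix(0, d_in, d_out),
    identity = {
      if (d_in != d_out) stopf("identity init needs d_in == d_out")
      diag(d_in)
    },
    stopf("unknown init '%s'", init))
  list(W = W, b = if (bias) numeric(d_out) else NULL)
}

#' Layer-normalization weights
#'
#' @param d channel count.
#' @param eps variance floor (default 1e-6).
#' @return list with unit `gain`, zero `shift` and `eps`.
#' @export
norm_weights <- function(d, eps = 1e-6) {
  list(gain = rep(1, d), shift = numeric(d), eps = eps)
}

#' Attention hyper-parameters
#'
#' @param n_heads number of attention heads `h`.
#' @param head_dim per-head channel count `d_k`.
#' @param softmax_dropout,output_dropout dropout rates in `[0, 1)`; both are
#'   ignored unless the forward pass runs in training mode.
#' @export
attention_params <- function(n_heads, head_dim,
                             softmax_dropout = 0.1, output_dropout = 0.1) {
  if (n_heads < 1L || head_dim < 1L) stopf("n_heads and head_dim must be >= 1")
  if (softmax_dropout < 0 || softmax_dropout >= 1 ||
      output_dropout < 0 || output_dropout >= 1) {
    stopf("dropout rates must lie in [0, 1)")
  }
  list(n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
       softmax_dropout = softmax_dropout, output_dropout = output_dropout)
}

## ---- linear -----------------------------------------------------------

linear_fwd <- function(x, w) {
  out <- x %*% w$W
  if (!is.null(w$b)) out <- sweep(out, 2L, w$b, "+")
  list(out = out, cache = list(x = x, w = w))
}

linear_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$w$W),
       dW = crossprod(cache$x, dout),
       db = if (is.null(cache$w$b)) NULL else colSums(dout))
}

## ---- layer norm (row-wise over channels) ------------------------------

ln_fwd <- function(x, w) {
  d <- ncol(x)
  if (length(w$gain) != d) stopf("layer norm dim %d != input dim %d",
                                 length(w$gain), d)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + w$eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, w$gain, "*"), 2L, w$shift, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, xc = xc, w = w))
}

ln_bwd <- function(dout, cache) {
  w <- cache$w
  d <- length(w$gain)
  dxhat <- sweep(dout, 2L, w$gain, "*")
  ## dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx,
       dgain = colSums(dout * cache$xhat),
       dshift = colSums(dout))
}

## ---- GELU (exact erf form) --------------------------------------------

gelu_fwd <- function(x) {
  phi <- stats::pnorm(x)
  list(out = x * phi, cache = list(x = x, phi = phi))
}

gelu_bwd <- function(dout, cache) {
  x <- cache$x
  dout * (cache$phi + x * stats::dnorm(x))
}

## ---- row-wise softmax -------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_rows_bwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

## ---- dropout ----------------------------------------------------------

## Inverted dropout; draws from the current RNG stream (caller seeds).
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- array(stats::rbinom(length(x), 1L, 1 - rate), dim = dim(x) %||% length(x))
  scale <- 1 / (1 - rate)
  list(out = x * keep * scale, cache = list(keep = keep, scale = scale))
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  dout * cache$keep * cache$scale
}
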