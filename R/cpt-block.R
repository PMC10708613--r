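## The cross-parallel transformer (C-PT) block: two branches with DD-gated
## query/key/value projections, cross-branch fusion into the left
## attention, a self-cross right attention whose values receive the left
## output, and an activation-function block in place of the FFN.

#' Weights for one C-PT branch
#'
#' @param d model width; @param n_dd DD layers per projection (0, 1 or 2).
#' @param bias include biases.
#' @export
cpt_branch_weights <- function(d = 768L, n_dd = 1L, bias = TRUE) {
  if (!n_dd %in% 0:2) stopf("dd_layers must be 0, 1 or 2")
  dd <- lapply(seq_len(n_dd), function(i) {
    list(q = linear_weights(d, d, bias = bias),
         k = linear_weights(d, d, bias = bias),
         v = linear_weights(d, d, bias = bias))
  })
  list(ln = norm_weights(d),
       wq = linear_weights(d, d, bias = bias),
       wk = linear_weights(d, d, bias = bias),
       wv = linear_weights(d, d, bias = bias),
       dd = dd,
       attn = mha_weights(d, bias = bias))
}

#' Weights for one C-PT layer
#'
#' Two branches, four fusion layer-norms (distinct parameterized norms,
#' not reuses of the branch input norms), the activation-block norm, and
#' optionally 1 or 2 parallel MLP blocks for the feed-forward ablations.
#'
#' @param d model width; @param n_dd DD layers (0-2); @param n_mlp MLP
#'   blocks (0-2; 0 selects the activation-function block).
#' @param d_mlp MLP hidden width; @param bias include biases.
#' @export
cpt_layer_weights <- function(d = 768L, n_dd = 1L, n_mlp = 0L,
                              d_mlp = 3072L, bias = TRUE) {
  if (!n_mlp %in% 0:2) stopf("mlp_layers must be 0, 1 or 2")
  list(left = cpt_branch_weights(d, n_dd, bias),
       right = cpt_branch_weights(d, n_dd, bias),
       fuse = list(ln_ql = norm_weights(d), ln_kl = norm_weights(d),
                   ln_qr = norm_weights(d), ln_kr = norm_weights(d)),
       ## the activation block exists only when no MLP replaces it
       act = if (n_mlp == 0L) norm_weights(d) else NULL,
       mlp = lapply(seq_len(n_mlp), function(i) mlp_weights(d, d_mlp, bias)))
}

#' Project the shared input into one branch's Q, K, V
#'
#' Both branches receive the same token matrix; each applies its own layer
#' norm followed by its own query/key/value projections.
#'
#' @param x token matrix; @param bw branch weights.
#' @return list with matrices `Q`, `K`, `V`.
#' @export
branch_project <- function(x, bw) {
  check_tokens(x)
  f <- branch_project_fwd(x, bw)
  list(Q = f$Q$out, K = f$K$out, V = f$V$out)
}

branch_project_fwd <- function(x, bw) {
  nf <- ln_fwd(x, bw$ln)
  list(nf = nf,
       Q = linear_fwd(nf$out, bw$wq),
       K = linear_fwd(nf$out, bw$wk),
       V = linear_fwd(nf$out, bw$wv))
}

#' Apply a branch's DD stack to its Q, K, V
#'
#' `n_dd = 0` is the identity; `n_dd = 2` applies two independent DD gates
#' sequentially.  Each of Q, K, V has its own DD weights.
#'
#' @param Q,K,V projected matrices; @param dd list of per-stack DD weights
#'   (as in [cpt_branch_weights()]); @param n_dd stack depth 0, 1 or 2.
#' @return list with gated `Q`, `K`, `V`.
#' @export
apply_dd_stack <- function(Q, K, V, dd, n_dd = length(dd)) {
  if (!n_dd %in% 0:2) stopf("dd stack depth must be 0, 1 or 2")
  f <- dd_stack_fwd(list(out = Q), list(out = K), list(out = V), dd[seq_len(n_dd)])
  list(Q = f$Q, K = f$K, V = f$V)
}

dd_stack_fwd <- function(Qf, Kf, Vf, dd) {
  Q <- Qf$out; K <- Kf$out; V <- Vf$out
  caches <- vector("list", length(dd))
  for (i in seq_along(dd)) {
    fq <- dd_fwd(Q, dd[[i]]$q); fk <- dd_fwd(K, dd[[i]]$k); fv <- dd_fwd(V, dd[[i]]$v)
    caches[[i]] <- list(q = fq, k = fk, v = fv)
    Q <- fq$out; K <- fk$out; V <- fv$out
  }
  list(Q = Q, K = K, V = V, caches = caches)
}

dd_stack_bwd <- function(dQ, dK, dV, caches) {
  grads <- vector("list", length(caches))
  for (i in rev(seq_along(caches))) {
    bq <- dd_bwd(dQ, caches[[i]]$q$cache)
    bk <- dd_bwd(dK, caches[[i]]$k$cache)
    bv <- dd_bwd(dV, caches[[i]]$v$cache)
    grads[[i]] <- list(q = list(dW = bq$dW, db = bq$db),
                       k = list(dW = bk$dW, db = bk$db),
                       v = list(dW = bv$dW, db = bv$db))
    dQ <- bq$dx; dK <- bk$dx; dV <- bv$dx
  }
  list(dQ = dQ, dK = dK, dV = dV, grads = grads)
}

#' Fuse the two branches' gated projections
#'
#' The left attention receives the cross-branch sums (queries and keys
#' re-normalized, values summed without a norm); the right attention's
#' queries and keys are its own gated projections, re-normalized.
#'
#' @param Ql,Kl,Vl,Qr,Kr,Vr gated projections of the left/right branches.
#' @param fw fusion norms (`ln_ql`, `ln_kl`, `ln_qr`, `ln_kr`).
#' @return list `Ql`, `Kl`, `Vl` (left attention inputs) and `Qr`, `Kr`
#'   (right attention query/key inputs).
#' @export
fuse_inputs <- function(Ql, Kl, Vl, Qr, Kr, Vr, fw) {
  if (!all(dim(Ql) == dim(Qr)) || !all(dim(Vl) == dim(Vr))) {
    stopf("branch shapes disagree")
  }
  f <- fuse_fwd(Ql, Kl, Vl, Qr, Kr, Vr, fw)
  list(Ql = f$ql$out, Kl = f$kl$out, Vl = f$Vl,
       Qr = f$qr$out, Kr = f$kr$out)
}

fuse_fwd <- function(Ql, Kl, Vl, Qr, Kr, Vr, fw) {
  list(ql = ln_fwd(Ql + Qr, fw$ln_ql),
       kl = ln_fwd(Kl + Kr, fw$ln_kl),
       Vl = Vl + Vr,
       qr = ln_fwd(Qr, fw$ln_qr),
       kr = ln_fwd(Kr, fw$ln_kr))
}

#' Left-branch fused self-attention
#'
#' Multi-head attention on the fused query/key/value triplet with the left
#' branch's output projection and dropout.
#'
#' @param Ql,Kl,Vl fused inputs from [fuse_inputs()].
#' @param w left-branch attention weights ([mha_weights()]).
#' @param p attention params; @param train enables dropout.
#' @export
left_attention <- function(Ql, Kl, Vl, w, p, train = FALSE) {
  multi_head_attention(Ql, Kl, Vl, w, p, train)
}

#' Right-branch self-cross attention
#'
#' The right branch's values are the sum of its own gated values and the
#' left branch's attention output, so the left block steers where the
#' right block looks; queries and keys are the right branch's own.
#'
#' @param Qr,Kr normalized right-branch query/key inputs.
#' @param Vr the right branch's gated values (pre-fusion).
#' @param O_left output of [left_attention()].
#' @param w right-branch attention weights; @param p attention params.
#' @param train enables dropout.
#' @export
right_attention <- function(Qr, Kr, Vr, O_left, w, p, train = FALSE) {
  if (!all(dim(Vr) == dim(O_left))) stopf("O_left shape differs from Vr")
  multi_head_attention(Qr, Kr, Vr + O_left, w, p, train)
}

#' Cross-parallel multi-head self-attention (C-PMHSA)
#'
#' Full two-branch composition: per-branch projection, DD gating, fusion,
#' left attention, right self-cross attention, and the sum of the two
#' branch outputs.  The residual to the layer input is applied by
#' [cpt_layer_forward()].
#'
#' @param z token matrix N x d.
#' @param w layer weights from [cpt_layer_weights()].
#' @param p attention params; @param train enables dropout.
#' @export
cpmhsa_forward <- function(z, w, p, train = FALSE) {
  check_tokens(z)
  cpmhsa_fwd(z, w, p, train)$out
}

cpmhsa_fwd <- function(z, w, p, train = FALSE) {
  pl <- branch_project_fwd(z, w$left)
  pr <- branch_project_fwd(z, w$right)
  dl <- dd_stack_fwd(pl$Q, pl$K, pl$V, w$left$dd)
  dr <- dd_stack_fwd(pr$Q, pr$K, pr$V, w$right$dd)
  fu <- fuse_fwd(dl$Q, dl$K, dl$V, dr$Q, dr$K, dr$V, w$fuse)
  ml <- mha_fwd(fu$ql$out, fu$kl$out, fu$Vl, w$left$attn, p, train)
  mr <- mha_fwd(fu$qr$out, fu$kr$out, dr$V + ml$out, w$right$attn, p, train)
  list(out = ml$out + mr$out,
       cache = list(pl = pl, pr = pr, dl = dl, dr = dr, fu = fu,
                    ml = ml, mr = mr))
}

cpmhsa_bwd <- function(dout, cache) {
  ## right attention first: its value input carries O_left
  mr <- mha_bwd(dout, cache$mr$cache)
  dVr_hat <- mr$dV              # toward the right branch's gated values
  dOl <- dout + mr$dV           # left output feeds the sum and Vr'
  ml <- mha_bwd(dOl, cache$ml$cache)
  ## fusion backward
  bql <- ln_bwd(ml$dQ, cache$fu$ql$cache)
  bkl <- ln_bwd(ml$dK, cache$fu$kl$cache)
  bqr <- ln_bwd(mr$dQ, cache$fu$qr$cache)
  bkr <- ln_bwd(mr$dK, cache$fu$kr$cache)
  dQl <- bql$dx;          dQr <- bql$dx + bqr$dx
  dKl <- bkl$dx;          dKr <- bkl$dx + bkr$dx
  dVl <- ml$dV;           dVr <- ml$dV + dVr_hat
  ## DD stacks
  sl <- dd_stack_bwd(dQl, dKl, dVl, cache$dl$caches)
  sr <- dd_stack_bwd(dQr, dKr, dVr, cache$dr$caches)
  ## branch projections
  blq <- linear_bwd(sl$dQ, cache$pl$Q$cache)
  blk <- linear_bwd(sl$dK, cache$pl$K$cache)
  blv <- linear_bwd(sl$dV, cache$pl$V$cache)
  brq <- linear_bwd(sr$dQ, cache$pr$Q$cache)
  brk <- linear_bwd(sr$dK, cache$pr$K$cache)
  brv <- linear_bwd(sr$dV, cache$pr$V$cache)
  bln_l <- ln_bwd(blq$dx + blk$dx + blv$dx, cache$pl$nf$cache)
  bln_r <- ln_bwd(brq$dx + brk$dx + brv$dx, cache$pr$nf$cache)
  list(
    dz = bln_l$dx + bln_r$dx,
    grads = list(
      left = list(ln = list(dgain = bln_l$dgain, dshift = bln_l$dshift),
                  wq = list(dW = blq$dW, db = blq$db),
                  wk = list(dW = blk$dW, db = blk$db),
                  wv = list(dW = blv$dW, db = blv$db),
                  dd = sl$grads,
                  attn = list(out_proj = ml$dout_proj)),
      right = list(ln = list(dgain = bln_r$dgain, dshift = bln_r$dshift),
                   wq = list(dW = brq$dW, db = brq$db),
                   wk = list(dW = brk$dW, db = brk$db),
                   wv = list(dW = brv$dW, db = brv$db),
                   dd = sr$grads,
                   attn = list(out_proj = mr$dout_proj)),
      fuse = list(ln_ql = list(dgain = bql$dgain, dshift = bql$dshift),
                  ln_kl = list(dgain = bkl$dgain, dshift = bkl$dshift),
                  ln_qr = list(dgain = bqr$dgain, dshift = bqr$dshift),
                  ln_kr = list(dgain = bkr$dgain, dshift = bkr$dshift))))
}

#' One C-PT layer
#'
#' `z' = C-PMHSA(z) + z`, then either the bare activation block
#' `GELU(LN(z'))` (canonical, `mlp_layers = 0`) or, for the feed-forward
#' ablations, `z' + sum_b MLP_b(z')` with 1 or 2 parallel MLP blocks.
#'
#' @param z token matrix; @param w weights from [cpt_layer_weights()].
#' @param p attention params; @param train enables dropout.
#' @param act_residual add a residual around the activation block
#'   (off by default, the block as defined).
#' @export
cpt_layer_forward <- function(z, w, p, train = FALSE, act_residual = FALSE) {
  check_tokens(z)
  cpt_layer_fwd(z, w, p, train, act_residual)$out
}

cpt_layer_fwd <- function(z, w, p, train = FALSE, act_residual = FALSE) {
  at <- cpmhsa_fwd(z, w, p, train)
  z1 <- at$out + z
  if (length(w$mlp) == 0L) {
    af <- act_fwd(z1, w$act, act_residual)
    list(out = af$out, cache = list(at = at, af = af, mlps = NULL))
  } else {
    out <- z1
    mlps <- vector("list", length(w$mlp))
    for (b in seq_along(w$mlp)) {
      mf <- mlp_fwd(z1, w$mlp[[b]])
      mlps[[b]] <- mf
      out <- out + mf$out
    }
    list(out = out, cache = list(at = at, af = NULL, mlps = mlps))
  }
}

cpt_layer_bwd <- function(dout, cache) {
  grads <- list()
  if (is.null(cache$mlps)) {
    ab <- act_bwd(dout, cache$af$cache)
    dz1 <- ab$dx
    grads$act <- list(dgain = ab$dgain, dshift = ab$dshift)
  } else {
    dz1 <- dout
    grads$mlp <- vector("list", length(cache$mlps))
    for (b in seq_along(cache$mlps)) {
      mb <- mlp_bwd(dout, cache$mlps[[b]]$cache)
      dz1 <- dz1 + mb$dx
      grads$mlp[[b]] <- mb$grads
    }
  }
  cb <- cpmhsa_bwd(dz1, cache$at$cache)
  grads <- c(cb$grads, grads)
  list(dz = cb$dz + dz1, grads = grads)
}


## ---- B > 2 generalization --------------------------------------------

## The cross pattern is defined for two branches.  For B > 2 the layer is
## realized as floor(B/2) independent cross-pairs whose outputs are
## summed, with an odd remaining branch falling back to plain multi-head
## self-attention.  This generalization is non-canonical (the published
## construction for B > 2 is not disclosed) and is excluded from the
## calibration reference rows.

#' Weights for a C-PT layer with more than two branches
#'
#' @param d model width; @param branches B >= 3; @param n_dd,n_mlp as in
#'   [cpt_layer_weights()]; @param d_mlp MLP width; @param bias biases.
#' @export
cpt_multi_layer_weights <- function(d, branches, n_dd = 1L, n_mlp = 0L,
                                    d_mlp = 3072L, bias = TRUE) {
  if (branches < 3L) stopf("use cpt_layer_weights for 2 branches")
  pairs <- lapply(seq_len(branches %/% 2L), function(i) {
    w <- cpt_layer_weights(d, n_dd, 0L, d_mlp, bias)
    w[c("left", "right", "fuse")]
  })
  odd <- NULL
  if (branches %% 2L == 1L) {
    odd <- cpt_branch_weights(d, n_dd, bias)
  }
  list(pairs = pairs, odd = odd,
       act = if (n_mlp == 0L) norm_weights(d) else NULL,
       mlp = lapply(seq_len(n_mlp), function(i) mlp_weights(d, d_mlp, bias)))
}

## plain self-attention of one C-PT-style branch (DD gates retained)
odd_branch_fwd <- function(z, bw, p, train) {
  pf <- branch_project_fwd(z, bw)
  df <- dd_stack_fwd(pf$Q, pf$K, pf$V, bw$dd)
  mh <- mha_fwd(df$Q, df$K, df$V, bw$attn, p, train)
  list(out = mh$out, cache = list(pf = pf, df = df, mh = mh))
}

odd_branch_bwd <- function(dout, cache) {
  mh <- mha_bwd(dout, cache$mh$cache)
  sb <- dd_stack_bwd(mh$dQ, mh$dK, mh$dV, cache$df$caches)
  bq <- linear_bwd(sb$dQ, cache$pf$Q$cache)
  bk <- linear_bwd(sb$dK, cache$pf$K$cache)
  bv <- linear_bwd(sb$dV, cache$pf$V$cache)
  bn <- ln_bwd(bq$dx + bk$dx + bv$dx, cache$pf$nf$cache)
  list(dz = bn$dx,
       grads = list(ln = list(dgain = bn$dgain, dshift = bn$dshift),
                    wq = list(dW = bq$dW, db = bq$db),
                    wk = list(dW = bk$dW, db = bk$db),
                    wv = list(dW = bv$dW, db = bv$db),
                    dd = sb$grads,
                    attn = list(out_proj = mh$dout_proj)))
}

cpt_multi_layer_fwd <- function(z, w, p, train = FALSE) {
  pcs <- lapply(w$pairs, function(pw) cpmhsa_fwd(z, pw, p, train))
  z1 <- z
  for (pc in pcs) z1 <- z1 + pc$out
  oc <- NULL
  if (!is.null(w$odd)) {
    oc <- odd_branch_fwd(z, w$odd, p, train)
    z1 <- z1 + oc$out
  }
  if (length(w$mlp) == 0L) {
    af <- act_fwd(z1, w$act)
    list(out = af$out, cache = list(pcs = pcs, oc = oc, af = af, mlps = NULL))
  } else {
    out <- z1
    mlps <- lapply(w$mlp, function(mw) mlp_fwd(z1, mw))
    for (mf in mlps) out <- out + mf$out
    list(out = out, cache = list(pcs = pcs, oc = oc, af = NULL, mlps = mlps))
  }
}

cpt_multi_layer_bwd <- function(dout, cache) {
  grads <- list()
  if (is.null(cache$mlps)) {
    ab <- act_bwd(dout, cache$af$cache)
    dz1 <- ab$dx
    grads$act <- list(dgain = ab$dgain, dshift = ab$dshift)
  } else {
    dz1 <- dout
    grads$mlp <- vector("list", length(cache$mlps))
    for (b in seq_along(cache$mlps)) {
      mb <- mlp_bwd(dout, cache$mlps[[b]]$cache)
      grads$mlp[[b]] <- mb$grads
      dz1 <- dz1 + mb$dx
    }
  }
  dz <- dz1
  grads$pairs <- vector("list", length(cache$pcs))
  for (i in seq_along(cache$pcs)) {
    cb <- cpmhsa_bwd(dz1, cache$pcs[[i]]$cache)
    grads$pairs[[i]] <- cb$grads
    dz <- dz + cb$dz
  }
  if (!is.null(cache$oc)) {
    ob <- odd_branch_bwd(dz1, cache$oc$cache)
    grads$odd <- ob$grads
    dz <- dz + ob$dz
  }
  list(dz = dz, grads = grads[c("pairs", "odd", "act", "mlp")])
}
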