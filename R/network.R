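## Full segmentation networks: a truncated residual-bottleneck CNN encoder
## feeding a transformer stack (serial ViT, parallel ViT, or C-PT) at 1/16
## scale, and a cascaded upsampling decoder with skip connections.

#' Network configuration
#'
#' @param variant `"cpt"`, `"parallel_vit"` or `"serial"`.
#' @param image_size input side length; must be divisible by `patch_size`.
#' @param n_classes label classes including background.
#' @param depth transformer layers `L`.
#' @param branches parallel branches `B` (1 for serial; the canonical C-PT
#'   cross pattern is defined for 2).
#' @param dd_layers,mlp_layers DD gates / MLP blocks per C-PT layer (0-2).
#' @param hidden_dim,heads,mlp_dim transformer dims (ViT-B defaults).
#' @param dropout dropout rate for both softmax and output sites.
#' @param bias carry biases on linear and DD layers.
#' @param in_channels input image channels (1 for grayscale CT).
#' @param patch_size embedded patch side at 1/16 scale (16).
#' @param width_factor scales every CNN/transformer width for desk-scale
#'   models (1 = full size); transformer dims are rounded to multiples of
#'   `heads`.
#' @param stage_blocks bottleneck counts of the three encoder stages.
#' @return a `cpt_config` list.
#' @export
cpt_config <- function(variant = c("cpt", "parallel_vit", "serial"),
                       image_size = 224L, n_classes = 9L,
                       depth = 7L, branches = 2L,
                       dd_layers = 1L, mlp_layers = 0L,
                       hidden_dim = 768L, heads = 12L, mlp_dim = 3072L,
                       dropout = 0.1, bias = TRUE,
                       in_channels = 1L, patch_size = 16L,
                       width_factor = 1, stage_blocks = c(3L, 4L, 9L)) {
  variant <- match.arg(variant)
  if (image_size %% patch_size != 0L) stopf("image_size must be divisible by %d", patch_size)
  if (depth < 1L) stopf("depth must be >= 1")
  if (variant == "serial") branches <- 1L
  if (branches < 1L) stopf("branches must be >= 1")
  if (variant == "parallel_vit" && branches < 2L) {
    stopf("parallel_vit needs branches >= 2")
  }
  if (variant == "cpt" && branches < 2L) {
    stopf("the cross-parallel block needs at least 2 branches")
  }
  if (!dd_layers %in% 0:2 || !mlp_layers %in% 0:2) {
    stopf("dd_layers and mlp_layers must be 0, 1 or 2")
  }
  w <- width_factor
  d <- max(1L, round(hidden_dim * w / heads)) * heads
  cfg <- list(
    variant = variant, image_size = as.integer(image_size),
    n_classes = as.integer(n_classes), depth = as.integer(depth),
    branches = as.integer(branches), dd_layers = as.integer(dd_layers),
    mlp_layers = as.integer(mlp_layers),
    hidden_dim = as.integer(d), heads = as.integer(heads),
    mlp_dim = as.integer(max(1L, round(mlp_dim * w))),
    dropout = dropout, bias = bias,
    in_channels = as.integer(in_channels), patch_size = as.integer(patch_size),
    width_factor = w, stage_blocks = as.integer(stage_blocks),
    ## trunk widths (see the methods vignette for how these were fixed)
    root_width = max(4L, round(48 * w)),
    stage_mid = pmax(4L, round(c(48, 80, 112) * w)),
    stage_out = pmax(8L, round(c(192, 320, 640) * w)),
    head_channels = max(8L, round(256 * w)),
    decoder_channels = pmax(4L, round(c(224, 96, 80, 32) * w))
  )
  class(cfg) <- "cpt_config"
  cfg
}

n_tokens <- function(cfg) (cfg$image_size %/% cfg$patch_size)^2

attn_params_of <- function(cfg) {
  attention_params(cfg$heads, cfg$hidden_dim %/% cfg$heads,
                   cfg$dropout, cfg$dropout)
}

## ---- model construction ----------------------------------------------

bottleneck_weights <- function(c_in, mid, c_out, stride) {
  w <- list(conv1 = conv_weights(1L, 1L, c_in, mid),
            gn1 = group_norm_weights(mid),
            conv2 = conv_weights(3L, 3L, mid, mid),
            gn2 = group_norm_weights(mid),
            conv3 = conv_weights(1L, 1L, mid, c_out),
            gn3 = group_norm_weights(c_out))
  if (c_in != c_out || stride != 1L) {
    w$down_conv <- conv_weights(1L, 1L, c_in, c_out)
    w$down_gn <- group_norm_weights(c_out)
  }
  w
}

transformer_layer_weights <- function(cfg) {
  d <- cfg$hidden_dim
  if (cfg$variant == "cpt") {
    if (cfg$branches > 2L) {
      cpt_multi_layer_weights(d, cfg$branches, cfg$dd_layers,
                              cfg$mlp_layers, cfg$mlp_dim, cfg$bias)
    } else {
      cpt_layer_weights(d, cfg$dd_layers, cfg$mlp_layers, cfg$mlp_dim,
                        cfg$bias)
    }
  } else {
    lapply(seq_len(cfg$branches), function(b) {
      vit_branch_weights(d, cfg$heads, cfg$mlp_dim, cfg$bias)
    })
  }
}

#' Build a segmentation model
#'
#' Materializes all trainable weights for a configuration with a
#' deterministic, seed-controlled initialization (truncated normal for
#' linear/DD/position weights, He-scaled normal for convolutions, unit
#' gain / zero shift for norms).
#'
#' @param cfg a [cpt_config()].
#' @param seed integer seed controlling the initialization.
#' @return a `cpt_model` list with elements `cfg` and `params`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cpt_config"))
  with_seed(seed, {
    enc <- list(root = list(conv = conv_weights(7L, 7L, cfg$in_channels,
                                                cfg$root_width),
                            gn = group_norm_weights(cfg$root_width)))
    c_in <- cfg$root_width
    enc$stages <- vector("list", 3L)
    for (s in 1:3) {
      stride <- c(1L, 2L, 2L)[s]
      blocks <- vector("list", cfg$stage_blocks[s])
      for (b in seq_len(cfg$stage_blocks[s])) {
        blocks[[b]] <- bottleneck_weights(c_in, cfg$stage_mid[s],
                                          cfg$stage_out[s],
                                          if (b == 1L) stride else 1L)
        c_in <- cfg$stage_out[s]
      }
      enc$stages[[s]] <- blocks
    }
    N <- n_tokens(cfg)
    embed <- list(conv = conv_weights(1L, 1L, cfg$stage_out[3L],
                                      cfg$hidden_dim, bias = TRUE),
                  pos = matrix(trunc_normal(N * cfg$hidden_dim), N,
                               cfg$hidden_dim),
                  ln = norm_weights(cfg$hidden_dim))
    transformer <- lapply(seq_len(cfg$depth), function(l) {
      transformer_layer_weights(cfg)
    })
    dc <- cfg$decoder_channels
    skip_ch <- c(cfg$stage_out[2L], cfg$stage_out[1L], cfg$root_width, 0L)
    in_ch <- cfg$head_channels
    blocks <- vector("list", 4L)
    for (i in 1:4) {
      blocks[[i]] <- list(conv1 = conv_weights(3L, 3L, in_ch + skip_ch[i], dc[i]),
                          gn1 = group_norm_weights(dc[i]),
                          conv2 = conv_weights(3L, 3L, dc[i], dc[i]),
                          gn2 = group_norm_weights(dc[i]))
      in_ch <- dc[i]
    }
    dec <- list(conv_more = list(conv = conv_weights(3L, 3L, cfg$hidden_dim,
                                                     cfg$head_channels),
                                 gn = group_norm_weights(cfg$head_channels)),
                blocks = blocks,
                head = conv_weights(1L, 1L, dc[4L], cfg$n_classes, bias = TRUE))
    structure(list(cfg = cfg,
                   params = list(enc = enc, embed = embed,
                                 transformer = transformer, dec = dec)),
              class = "cpt_model")
  })
}

#' @export
print.cpt_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<cpt_model> %s %dx%d (depth %d x %d branches, dd %d, mlp %d)\n",
              cfg$variant, cfg$image_size, cfg$image_size, cfg$depth,
              cfg$branches, cfg$dd_layers, cfg$mlp_layers))
  cat(sprintf("  hidden %d, heads %d, classes %d, ~%.2f M parameters\n",
              cfg$hidden_dim, cfg$heads, cfg$n_classes,
              model_param_count(x) / 1e6))
  invisible(x)
}

## ---- forward / backward ----------------------------------------------

bottleneck_fwd <- function(x, w, stride) {
  c1 <- conv2d_fwd(x, w$conv1); g1 <- gn_fwd(c1$out, w$gn1); r1 <- relu_fwd(g1$out)
  c2 <- conv2d_fwd(r1$out, w$conv2, stride = stride, pad = 1L)
  g2 <- gn_fwd(c2$out, w$gn2); r2 <- relu_fwd(g2$out)
  c3 <- conv2d_fwd(r2$out, w$conv3); g3 <- gn_fwd(c3$out, w$gn3)
  if (!is.null(w$down_conv)) {
    dcv <- conv2d_fwd(x, w$down_conv, stride = stride)
    dgn <- gn_fwd(dcv$out, w$down_gn)
    res <- dgn$out
  } else {
    dcv <- NULL; dgn <- NULL; res <- x
  }
  rf <- relu_fwd(g3$out + res)
  list(out = rf$out,
       cache = list(c1 = c1, g1 = g1, r1 = r1, c2 = c2, g2 = g2, r2 = r2,
                    c3 = c3, g3 = g3, dcv = dcv, dgn = dgn, rf = rf,
                    identity = is.null(dcv)))
}

bottleneck_bwd <- function(dout, cache) {
  dsum <- relu_bwd(dout, cache$rf$cache)
  b3 <- gn_bwd(dsum, cache$g3$cache)
  cb3 <- conv2d_bwd(b3$dx, cache$c3$cache)
  dr2 <- relu_bwd(cb3$dx, cache$r2$cache)
  b2 <- gn_bwd(dr2, cache$g2$cache)
  cb2 <- conv2d_bwd(b2$dx, cache$c2$cache)
  dr1 <- relu_bwd(cb2$dx, cache$r1$cache)
  b1 <- gn_bwd(dr1, cache$g1$cache)
  cb1 <- conv2d_bwd(b1$dx, cache$c1$cache)
  g <- list(conv1 = list(W = cb1$dW, b = cb1$db),
            gn1 = list(gain = b1$dgain, shift = b1$dshift),
            conv2 = list(W = cb2$dW, b = cb2$db),
            gn2 = list(gain = b2$dgain, shift = b2$dshift),
            conv3 = list(W = cb3$dW, b = cb3$db),
            gn3 = list(gain = b3$dgain, shift = b3$dshift))
  if (cache$identity) {
    dx <- cb1$dx + dsum
  } else {
    bd <- gn_bwd(dsum, cache$dgn$cache)
    cbd <- conv2d_bwd(bd$dx, cache$dcv$cache)
    dx <- cb1$dx + cbd$dx
    g$down_conv <- list(W = cbd$dW, b = cbd$db)
    g$down_gn <- list(gain = bd$dgain, shift = bd$dshift)
  }
  list(dx = dx, grads = g)
}

encoder_fwd <- function(params, cfg, image) {
  rc <- conv2d_fwd(image, params$root$conv, stride = 2L, pad = 3L)
  rg <- gn_fwd(rc$out, params$root$gn)
  rr <- relu_fwd(rg$out)
  mp <- maxpool_fwd(rr$out)
  x <- mp$out
  stages <- vector("list", 3L)
  skips <- list()
  for (s in 1:3) {
    stride <- c(1L, 2L, 2L)[s]
    caches <- vector("list", length(params$stages[[s]]))
    for (b in seq_along(params$stages[[s]])) {
      f <- bottleneck_fwd(x, params$stages[[s]][[b]],
                          if (b == 1L) stride else 1L)
      caches[[b]] <- f$cache
      x <- f$out
    }
    stages[[s]] <- caches
    if (s <= 2L) skips[[s]] <- x
  }
  list(out = x, skips = list(skips[[2L]], skips[[1L]], rr$out),
       cache = list(rc = rc, rg = rg, rr = rr, mp = mp, stages = stages))
}

encoder_bwd <- function(dout, dskips, params, cache) {
  g <- list(stages = vector("list", 3L))
  dx <- dout
  for (s in 3:1) {
    caches <- cache$stages[[s]]
    gs <- vector("list", length(caches))
    for (b in rev(seq_along(caches))) {
      bb <- bottleneck_bwd(dx, caches[[b]])
      gs[[b]] <- bb$grads
      dx <- bb$dx
    }
    g$stages[[s]] <- gs
    if (s == 3L) dx <- dx + dskips[[1L]]   # stage-2 output skip
    if (s == 2L) dx <- dx + dskips[[2L]]   # stage-1 output skip
  }
  dmp <- maxpool_bwd(dx, cache$mp$cache)
  drr <- relu_bwd(dmp + dskips[[3L]], cache$rr$cache)
  brg <- gn_bwd(drr, cache$rg$cache)
  brc <- conv2d_bwd(brg$dx, cache$rc$cache)
  g$root <- list(conv = list(W = brc$dW, b = brc$db),
                 gn = list(gain = brg$dgain, shift = brg$dshift))
  list(dimage = brc$dx, grads = g)
}

transformer_fwd <- function(params, cfg, tokens, train) {
  p <- attn_params_of(cfg)
  caches <- vector("list", cfg$depth)
  x <- tokens
  for (l in seq_len(cfg$depth)) {
    f <- if (cfg$variant == "cpt") {
      if (cfg$branches > 2L) {
        cpt_multi_layer_fwd(x, params[[l]], p, train)
      } else {
        cpt_layer_fwd(x, params[[l]], p, train)
      }
    } else {
      vit_layer_fwd(x, params[[l]], p, train)
    }
    caches[[l]] <- f$cache
    x <- f$out
  }
  list(out = x, cache = caches)
}

transformer_bwd <- function(dout, cfg, cache) {
  grads <- vector("list", cfg$depth)
  dx <- dout
  for (l in rev(seq_len(cfg$depth))) {
    b <- if (cfg$variant == "cpt") {
      if (cfg$branches > 2L) {
        cpt_multi_layer_bwd(dx, cache[[l]])
      } else {
        cpt_layer_bwd(dx, cache[[l]])
      }
    } else {
      vit_layer_bwd(dx, cache[[l]])
    }
    grads[[l]] <- b$grads
    dx <- b$dz %||% b$dx
  }
  list(dtokens = dx, grads = grads)
}

decoder_fwd <- function(params, cfg, feat, skips) {
  cm <- conv2d_fwd(feat, params$conv_more$conv, pad = 1L)
  gm <- gn_fwd(cm$out, params$conv_more$gn)
  rm <- relu_fwd(gm$out)
  x <- rm$out
  blocks <- vector("list", 4L)
  for (i in 1:4) {
    up <- upsample2_fwd(x)
    if (i <= 3L) {
      skip <- skips[[i]]
      xin <- array(c(up$out, skip), c(dim(up$out)[1:2],
                                      dim(up$out)[3L] + dim(skip)[3L]))
      nskip <- dim(skip)[3L]
    } else {
      xin <- up$out
      nskip <- 0L
    }
    w <- params$blocks[[i]]
    c1 <- conv2d_fwd(xin, w$conv1, pad = 1L); g1 <- gn_fwd(c1$out, w$gn1)
    r1 <- relu_fwd(g1$out)
    c2 <- conv2d_fwd(r1$out, w$conv2, pad = 1L); g2 <- gn_fwd(c2$out, w$gn2)
    r2 <- relu_fwd(g2$out)
    blocks[[i]] <- list(up = up, nskip = nskip, c1 = c1, g1 = g1, r1 = r1,
                        c2 = c2, g2 = g2, r2 = r2)
    x <- r2$out
  }
  hd <- conv2d_fwd(x, params$head)
  list(out = hd$out,
       cache = list(cm = cm, gm = gm, rm = rm, blocks = blocks, hd = hd))
}

decoder_bwd <- function(dout, params, cache) {
  hb <- conv2d_bwd(dout, cache$hd$cache)
  g <- list(head = list(W = hb$dW, b = hb$db), blocks = vector("list", 4L))
  dx <- hb$dx
  dskips <- vector("list", 3L)
  for (i in 4:1) {
    bc <- cache$blocks[[i]]
    dr2 <- relu_bwd(dx, bc$r2$cache)
    b2 <- gn_bwd(dr2, bc$g2$cache)
    cb2 <- conv2d_bwd(b2$dx, bc$c2$cache)
    dr1 <- relu_bwd(cb2$dx, bc$r1$cache)
    b1 <- gn_bwd(dr1, bc$g1$cache)
    cb1 <- conv2d_bwd(b1$dx, bc$c1$cache)
    g$blocks[[i]] <- list(conv1 = list(W = cb1$dW, b = cb1$db),
                          gn1 = list(gain = b1$dgain, shift = b1$dshift),
                          conv2 = list(W = cb2$dW, b = cb2$db),
                          gn2 = list(gain = b2$dgain, shift = b2$dshift))
    din <- cb1$dx
    if (bc$nskip > 0L) {
      nc <- dim(din)[3L] - bc$nskip
      dskips[[i]] <- din[, , (nc + 1L):dim(din)[3L], drop = FALSE]
      din <- din[, , seq_len(nc), drop = FALSE]
    }
    dx <- upsample2_bwd(din, bc$up$cache)
  }
  drm <- relu_bwd(dx, cache$rm$cache)
  bgm <- gn_bwd(drm, cache$gm$cache)
  bcm <- conv2d_bwd(bgm$dx, cache$cm$cache)
  g$conv_more <- list(conv = list(W = bcm$dW, b = bcm$db),
                      gn = list(gain = bgm$dgain, shift = bgm$dshift))
  list(dfeat = bcm$dx, dskips = dskips, grads = g)
}

network_fwd <- function(model, image, train = FALSE) {
  cfg <- model$cfg
  if (!all(dim(image)[1:2] == cfg$image_size)) {
    stopf("image is %dx%d but the model expects %dx%d",
          dim(image)[1L], dim(image)[2L], cfg$image_size, cfg$image_size)
  }
  ef <- encoder_fwd(model$params$enc, cfg, image)
  pe <- conv2d_fwd(ef$out, model$params$embed$conv)
  grid <- dim(pe$out)[1L]
  tokens <- matrix(pe$out, grid * grid, cfg$hidden_dim) + model$params$embed$pos
  tf <- transformer_fwd(model$params$transformer, cfg, tokens, train)
  lnf <- ln_fwd(tf$out, model$params$embed$ln)
  feat <- array(lnf$out, c(grid, grid, cfg$hidden_dim))
  df <- decoder_fwd(model$params$dec, cfg, feat, ef$skips)
  list(out = df$out,
       cache = list(ef = ef, pe = pe, grid = grid, tf = tf, lnf = lnf,
                    df = df))
}

network_bwd <- function(model, dlogits, cache) {
  cfg <- model$cfg
  db <- decoder_bwd(dlogits, model$params$dec, cache$df$cache)
  dfeat <- matrix(db$dfeat, cache$grid^2, cfg$hidden_dim)
  bl <- ln_bwd(dfeat, cache$lnf$cache)
  tb <- transformer_bwd(bl$dx, cfg, cache$tf$cache)
  dpos <- tb$dtokens
  dpe <- array(tb$dtokens, c(cache$grid, cache$grid, cfg$hidden_dim))
  pb <- conv2d_bwd(dpe, cache$pe$cache)
  eb <- encoder_bwd(pb$dx, db$dskips, model$params$enc, cache$ef$cache)
  grads <- list(enc = eb$grads,
                embed = list(conv = list(W = pb$dW, b = pb$db),
                             pos = dpos,
                             ln = list(gain = bl$dgain, shift = bl$dshift)),
                transformer = rename_grads(tb$grads),
                dec = db$grads)
  grads
}

## map dW/db/dgain/dshift leaf names onto the parameter layout
rename_grads <- function(g) {
  if (!is.list(g)) return(g)
  nm <- names(g)
  if (!is.null(nm)) {
    map <- c(dW = "W", db = "b", dgain = "gain", dshift = "shift")
    hit <- nm %in% names(map)
    nm[hit] <- map[nm[hit]]
    names(g) <- nm
  }
  lapply(g, rename_grads)
}

## ---- public inference surface -----------------------------------------

#' Encode an image into transformer tokens and decoder skip features
#'
#' @param model a built model; @param image `(H, W, C)` array (a plain
#'   `H x W` matrix is treated as one channel).
#' @return list with `tokens` (`N x d`) and `skips` (three feature maps at
#'   1/8, 1/4 and 1/2 scale, decoder order).
#' @export
hybrid_encode <- function(model, image) {
  image <- as_image(image, model$cfg)
  cfg <- model$cfg
  ef <- encoder_fwd(model$params$enc, cfg, image)
  pe <- conv2d_fwd(ef$out, model$params$embed$conv)
  grid <- dim(pe$out)[1L]
  tokens <- matrix(pe$out, grid * grid, cfg$hidden_dim) + model$params$embed$pos
  list(tokens = tokens, skips = ef$skips)
}

#' Decode transformer tokens to per-pixel class logits
#'
#' Tokens are reshaped to the 1/16-scale grid (their count must be a
#' perfect square), passed through the cascaded upsampler with skip
#' concatenation, and projected to `n_classes` logits at input resolution.
#'
#' @param model a built model; @param tokens `N x d` matrix;
#' @param skips skip features as returned by [hybrid_encode()].
#' @export
decode_cup <- function(model, tokens, skips) {
  cfg <- model$cfg
  grid <- sqrt(nrow(tokens))
  if (grid != round(grid)) stopf("token count %d is not a perfect square",
                                 nrow(tokens))
  lnf <- ln_fwd(tokens, model$params$embed$ln)
  feat <- array(lnf$out, c(grid, grid, cfg$hidden_dim))
  decoder_fwd(model$params$dec, cfg, feat, skips)$out
}

as_image <- function(image, cfg) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  storage.mode(image) <- "double"
  image
}

#' Forward pass returning per-pixel class probabilities
#'
#' Evaluation-mode forward (dropout off, deterministic); softmax over
#' classes at every pixel.
#'
#' @param model a built model; @param image input slice.
#' @return `(H, W, n_classes)` array of probabilities summing to 1 per
#'   pixel.
#' @export
forward_segment <- function(model, image) {
  image <- as_image(image, model$cfg)
  logits <- network_fwd(model, image, train = FALSE)$out
  d <- dim(logits)
  pm <- softmax_rows(matrix(logits, d[1L] * d[2L], d[3L]))
  array(pm, d)
}

#' Predicted label map for one slice
#' @param model a built model; @param image input slice.
#' @return integer `H x W` matrix of class labels in `0 .. n_classes-1`.
#' @export
predict_slice <- function(model, image) {
  p <- forward_segment(model, image)
  d <- dim(p)
  lab <- max.col(matrix(p, d[1L] * d[2L], d[3L]), ties.method = "first") - 1L
  matrix(lab, d[1L], d[2L])
}

## ---- config YAML round-trip -------------------------------------------

#' Write a network configuration to YAML
#'
#' Uses the external key `parallelism` for the branch count.
#' @param cfg a [cpt_config()]; @param path output file.
#' @export
write_cpt_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cpt_config"))
  y <- list(variant = cfg$variant, image_size = cfg$image_size,
            n_classes = cfg$n_classes, depth = cfg$depth,
            parallelism = cfg$branches, dd_layers = cfg$dd_layers,
            mlp_layers = cfg$mlp_layers, hidden_dim = cfg$hidden_dim,
            heads = cfg$heads, mlp_dim = cfg$mlp_dim,
            dropout = cfg$dropout, bias = cfg$bias,
            in_channels = cfg$in_channels, patch_size = cfg$patch_size,
            width_factor = cfg$width_factor)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a network configuration from YAML
#' @param path YAML file with [cpt_config()] keys (`parallelism` maps to
#'   `branches`).
#' @export
read_cpt_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$parallelism)) {
    y$branches <- y$parallelism
    y$parallelism <- NULL
  }
  ## widths are derived from width_factor; hidden/mlp dims are re-derived
  keep <- intersect(names(y), names(formals(cpt_config)))
  cfg <- do.call(cpt_config, y[keep])
  cfg$hidden_dim <- y$hidden_dim %||% cfg$hidden_dim
  cfg$mlp_dim <- y$mlp_dim %||% cfg$mlp_dim
  cfg
}
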