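## Desk-scale training harness: SGD with momentum and weight decay on a
## combined cross-entropy + soft-Dice pixel loss, slice-to-volume
## inference, and an experiment-grid runner.

#' Training configuration
#'
#' Defaults follow the reference optimizer settings (SGD, learning rate
#' 0.01, momentum 0.9, weight decay 1e-4, batch 24, 14k iterations);
#' [desk_profile()] provides the reduced settings used by the tests.
#'
#' @param lr,momentum,weight_decay SGD hyper-parameters.
#' @param batch_size slices per iteration; @param max_iterations budget.
#' @param seed RNG seed for sampling, augmentation and dropout.
#' @param augment_rotate random in-plane rotation up to
#'   `rotate_degrees`; @param augment_flip random horizontal flip.
#' @param rotate_degrees rotation amplitude (degrees).
#' @param ce_weight,dice_weight loss mixing weights.
#' @param eval_every compute training DSC every this many iterations
#'   (0 = never); @param stop_dsc stop early once training DSC reaches
#'   this value (`NULL` = run the full budget).
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 24L, max_iterations = 14000L,
                         seed = 42L, augment_rotate = TRUE,
                         augment_flip = TRUE, rotate_degrees = 20,
                         ce_weight = 0.5, dice_weight = 0.5,
                         eval_every = 0L, stop_dsc = NULL) {
  if (lr <= 0) stopf("lr must be positive")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), augment_rotate = augment_rotate,
                 augment_flip = augment_flip, rotate_degrees = rotate_degrees,
                 ce_weight = ce_weight, dice_weight = dice_weight,
                 eval_every = as.integer(eval_every), stop_dsc = stop_dsc),
            class = "train_config")
}

#' Reduced desk-scale training profile
#' @param ... overrides passed to [train_config()].
#' @export
desk_profile <- function(...) {
  args <- list(batch_size = 4L, max_iterations = 500L,
               augment_rotate = FALSE, augment_flip = FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

## ---- loss -------------------------------------------------------------

## softmax CE + soft Dice on one slice; returns loss terms and dlogits
seg_loss <- function(logits, labels, n_classes, ce_weight, dice_weight,
                     smooth = 1e-5) {
  d <- dim(logits)
  npix <- d[1L] * d[2L]
  z <- matrix(logits, npix, n_classes)
  p <- softmax_rows(z)
  y <- matrix(0, npix, n_classes)
  y[cbind(seq_len(npix), as.integer(labels) + 1L)] <- 1
  ## cross entropy
  pc <- pmax(p[y == 1], 1e-12)
  ce <- -mean(log(pc))
  dLdp_ce <- -(y / pmax(p, 1e-12)) / npix
  ## soft dice averaged over classes
  num <- 2 * colSums(p * y) + smooth
  den <- colSums(p) + colSums(y) + smooth
  dice <- mean(num / den)
  dLdp_dice <- -(sweep(y * 2, 2L, den, "*") - matrix(num, npix, n_classes,
                                                     byrow = TRUE)) /
    matrix(den^2, npix, n_classes, byrow = TRUE) / n_classes
  dLdp <- ce_weight * dLdp_ce + dice_weight * dLdp_dice
  dz <- p * (dLdp - rowSums(dLdp * p))
  list(loss = ce_weight * ce + dice_weight * (1 - dice),
       ce = ce, dice = dice,
       dlogits = array(dz, d))
}

## ---- parameter updates ------------------------------------------------

## recursive SGD step (PyTorch semantics: v = mu v + g + wd w; w -= lr v)
sgd_step <- function(params, grads, state, tc) {
  walk <- function(w, g, v) {
    if (is.list(w)) {
      if (is.null(v)) v <- vector("list", length(w))
      nms <- names(w)
      for (i in seq_along(w)) {
        nm <- if (is.null(nms)) "" else nms[i]
        if (nm %in% c("eps", "groups")) next
        gi <- if (nzchar(nm)) g[[nm]] else if (i <= length(g)) g[[i]] else NULL
        if (is.null(gi)) next
        res <- walk(w[[i]], gi, if (i <= length(v)) v[[i]] else NULL)
        w[[i]] <- res$w
        v[[i]] <- res$v
      }
      return(list(w = w, v = v))
    }
    if (!is.numeric(w)) return(list(w = w, v = v))
    gg <- g + tc$weight_decay * w
    if (is.null(v)) v <- gg else v <- tc$momentum * v + gg
    w <- w - tc$lr * v
    attrs <- attributes(g)
    if (!is.null(attrs$kernel)) attr(w, "kernel") <- attrs$kernel
    list(w = w, v = v)
  }
  res <- walk(params, grads, state)
  res
}

## accumulate two grad trees (same shape)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- acc_grads(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

#' Flatten a parameter (or gradient) tree into named numeric leaves
#' @param params nested parameter list of a `cpt_model`.
#' @export
flatten_params <- function(params) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      nms <- names(x) %||% as.character(seq_along(x))
      for (i in seq_along(x)) {
        nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
        if (nm %in% c("eps", "groups")) next
        walk(x[[i]], paste(path, nm, sep = "."))
      }
    } else if (is.numeric(x)) {
      out[[sub("^\\.", "", path)]] <<- x
    }
  }
  walk(params, "")
  out
}

## ---- augmentation -----------------------------------------------------

rotate_pair <- function(img, lab, angle) {
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gr <- matrix(seq_len(H), H, W) - cy
  gc <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sr <- round(cos(th) * gr - sin(th) * gc + cy)   # nearest-neighbour
  sc <- round(sin(th) * gr + cos(th) * gc + cx)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  idx <- cbind(as.vector(pmin(pmax(sr, 1L), H)),
               as.vector(pmin(pmax(sc, 1L), W)))
  img2 <- matrix(0, H, W); lab2 <- matrix(0L, H, W)
  img2[ok] <- img[idx][ok]
  lab2[ok] <- lab[idx][ok]
  list(img = img2, lab = lab2)
}

augment_slice <- function(img, lab, tc) {
  if (tc$augment_flip && stats::runif(1) < 0.5) {
    img <- img[, ncol(img):1]
    lab <- lab[, ncol(lab):1]
  }
  if (tc$augment_rotate) {
    ang <- stats::runif(1, -tc$rotate_degrees, tc$rotate_degrees)
    rp <- rotate_pair(img, lab, ang)
    img <- rp$img; lab <- rp$lab
  }
  list(img = img, lab = lab)
}

## ---- training loop ----------------------------------------------------

#' Train a segmentation model
#'
#' SGD with momentum and weight decay on `ce_weight * CE +
#' dice_weight * (1 - softDice)`.  Deterministic for a fixed seed and
#' thread count; aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model a built `cpt_model`.
#' @param volumes list of training volumes (fields `slices`, `labels`).
#' @param tc a [train_config()] or [desk_profile()].
#' @return list with the trained `model`, `log` (data frame of per-
#'   iteration losses and periodic training DSC) and `stopped_early`.
#' @export
train_model <- function(model, volumes, tc = desk_profile()) {
  if (!length(volumes)) stopf("training set is empty")
  cfg <- model$cfg
  slices <- list()
  for (v in volumes) {
    for (s in seq_len(dim(v$slices)[1L])) {
      slices[[length(slices) + 1L]] <-
        list(img = matrix(v$slices[s, , ], dim(v$slices)[2L]),
             lab = matrix(v$labels[s, , ], dim(v$labels)[2L]))
    }
  }
  state <- NULL
  log_iter <- integer(); log_loss <- numeric(); log_ce <- numeric()
  log_dice <- numeric(); log_dsc <- numeric()
  stopped_early <- FALSE
  with_seed(tc$seed, {
    for (it in seq_len(tc$max_iterations)) {
      pick <- sample.int(length(slices), tc$batch_size, replace = TRUE)
      grads <- NULL
      loss <- 0; ce <- 0; dice <- 0
      for (j in pick) {
        sl <- slices[[j]]
        if (tc$augment_flip || tc$augment_rotate) {
          sl <- augment_slice(sl$img, sl$lab, tc)
        }
        fw <- network_fwd(model, as_image(sl$img, cfg), train = TRUE)
        ls <- seg_loss(fw$out, sl$lab, cfg$n_classes,
                       tc$ce_weight, tc$dice_weight)
        g <- network_bwd(model, ls$dlogits / tc$batch_size, fw$cache)
        grads <- acc_grads(grads, g)
        loss <- loss + ls$loss / tc$batch_size
        ce <- ce + ls$ce / tc$batch_size
        dice <- dice + ls$dice / tc$batch_size
      }
      if (!is.finite(loss)) {
        stopf("training diverged at iteration %d (loss %g)", it, loss)
      }
      upd <- sgd_step(model$params, grads, state, tc)
      model$params <- upd$w
      state <- upd$v
      log_iter <- c(log_iter, it); log_loss <- c(log_loss, loss)
      log_ce <- c(log_ce, ce); log_dice <- c(log_dice, dice)
      dsc_now <- NA_real_
      if (tc$eval_every > 0L && it %% tc$eval_every == 0L) {
        dsc_now <- training_dsc(model, volumes)
        if (!is.null(tc$stop_dsc) && dsc_now >= tc$stop_dsc) {
          log_dsc <- c(log_dsc, dsc_now)
          stopped_early <- TRUE
          break
        }
      }
      log_dsc <- c(log_dsc, dsc_now)
    }
  })
  list(model = model,
       log = data.frame(iter = log_iter, loss = log_loss, ce = log_ce,
                        soft_dice = log_dice, train_dsc = log_dsc),
       stopped_early = stopped_early)
}

## mean foreground DSC of argmax predictions on the training volumes
training_dsc <- function(model, volumes) {
  preds <- lapply(volumes, function(v) infer_volume(model, v))
  rep <- evaluate_volumes(NULL, volumes, predictions = preds)
  ## restrict to classes present; DSC column already excludes background
  mean(rep$per_class$dsc, na.rm = TRUE)
}

#' Slice-wise inference stacked into a 3D label volume
#'
#' @param model a built `cpt_model`; @param volume a phantom-style volume.
#' @return integer `S x H x W` label array.
#' @export
infer_volume <- function(model, volume) {
  d <- dim(volume$slices)
  out <- array(0L, d)
  for (s in seq_len(d[1L])) {
    out[s, , ] <- predict_slice(model, matrix(volume$slices[s, , ], d[2L]))
  }
  out
}

#' Run an accounting (and optionally training) grid
#'
#' Builds each configuration, always runs the accounting engine, and
#' optionally trains/evaluates on a phantom dataset; per-variant failures
#' are recorded and the grid continues.
#'
#' @param configs list of [cpt_config()]s.
#' @param convention counting convention for the accounting columns.
#' @param train_volumes,test_volumes optional phantom volumes enabling
#'   desk-scale training; @param tc training configuration.
#' @param seed build seed.
#' @return data frame, one row per variant.
#' @export
run_experiment_grid <- function(configs, convention = default_convention(),
                                train_volumes = NULL, test_volumes = NULL,
                                tc = desk_profile(), seed = 1L) {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    res <- tryCatch({
      rep <- account(cfg, convention = convention)
      dsc <- NA_real_
      if (!is.null(train_volumes)) {
        model <- build_model(cfg, seed = derive_seed(seed, i))
        tr <- train_model(model, train_volumes, tc)
        ev <- evaluate_volumes(tr$model, test_volumes %||% train_volumes)
        dsc <- ev$average$dsc
      }
      data.frame(variant = cfg$variant, size = cfg$image_size,
                 branches = cfg$branches, layers = cfg$depth,
                 dd = cfg$dd_layers, mlp = cfg$mlp_layers,
                 params_m = rep$params_millions, flops_g = rep$flops_giga,
                 dsc = dsc, error = NA_character_)
    }, error = function(e) {
      data.frame(variant = cfg$variant, size = cfg$image_size,
                 branches = cfg$branches, layers = cfg$depth,
                 dd = cfg$dd_layers, mlp = cfg$mlp_layers,
                 params_m = NA_real_, flops_g = NA_real_, dsc = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  if (!length(rows)) {
    return(data.frame(variant = character(), size = integer(),
                      branches = integer(), layers = integer(),
                      dd = integer(), mlp = integer(), params_m = numeric(),
                      flops_g = numeric(), dsc = numeric(),
                      error = character()))
  }
  do.call(rbind, rows)
}
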