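## Segmentation evaluation: Dice, 95th-percentile Hausdorff distance with
## anisotropic spacing, confusion-matrix rates, and per-organ evaluation
## of 3D volumes reconstructed from per-slice 2D predictions.

as_mask <- function(m, name) {
  if (is.logical(m)) return(m)
  if (is.numeric(m)) return(m != 0)
  stopf("%s must be a logical or numeric mask", name)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks; defined as 1 when both
#' masks are empty.
#'
#' @param pred,truth binary masks of identical shape.
#' @export
dice_coefficient <- function(pred, truth) {
  pred <- as_mask(pred, "pred"); truth <- as_mask(truth, "truth")
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    stopf("mask shapes differ")
  }
  na <- sum(pred); nb <- sum(truth)
  if (na + nb == 0L) return(1)
  2 * sum(pred & truth) / (na + nb)
}

## voxel coordinates (in mm) of a mask's foreground, one row per voxel
mask_coords <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (is.vector(idx)) idx <- matrix(idx, ncol = 1L)
  sweep(idx, 2L, spacing[seq_len(ncol(idx))], "*")
}

## for each row of a, distance to the nearest row of b (chunked BLAS)
nn_dist <- function(a, b, chunk = 1024L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    aa <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), nb2, "+") - 2 * tcrossprod(aa, b)
    out[i:j] <- sqrt(pmax(apply(d2, 1L, min), 0))
    i <- j + 1L
  }
  out
}

## boundary voxels: foreground with at least one 6-neighbour outside
boundary_mask <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) mask <- array(mask, c(d, 1L))
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

#' 95th-percentile Hausdorff distance
#'
#' Symmetric HD95 between two masks in physical units: the maximum of the
#' two directed 95th-percentile nearest-surface distances (the form used
#' throughout this literature).  A sum of the two directed distances is
#' available via `combine = "sum"` for fidelity experiments.
#'
#' @param pred,truth nonempty binary masks of identical shape (2D or 3D).
#' @param spacing physical voxel size per axis, mm.
#' @param combine `"max"` (standard) or `"sum"` of directed distances.
#' @param surface `"voxels"` (all foreground voxels, the common
#'   implementation convention) or `"boundary"` (6-connectivity surface).
#' @return distance in mm, or `NA_real_` if either mask is empty.
#' @export
hausdorff95 <- function(pred, truth, spacing = c(1, 1, 1),
                        combine = c("max", "sum"),
                        surface = c("voxels", "boundary")) {
  combine <- match.arg(combine)
  surface <- match.arg(surface)
  pred <- as_mask(pred, "pred"); truth <- as_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth))) stopf("mask shapes differ")
  if (!any(pred) || !any(truth)) return(NA_real_)
  if (surface == "boundary") {
    pred <- boundary_mask(pred)
    truth <- boundary_mask(truth)
  }
  a <- mask_coords(pred, spacing)
  b <- mask_coords(truth, spacing)
  dab <- stats::quantile(nn_dist(a, b), 0.95, names = FALSE)
  dba <- stats::quantile(nn_dist(b, a), 0.95, names = FALSE)
  if (combine == "max") max(dab, dba) else dab + dba
}

#' Confusion-matrix rates for a binary segmentation
#'
#' Accuracy, F1, sensitivity (recall) and precision from the TP/TN/FP/FN
#' tally.  Rates with a zero denominator are returned as 0 and flagged.
#'
#' @param pred,truth binary masks of identical shape.
#' @return named list with the four rates and `undefined`, the names of
#'   any zero-denominator rates.
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as_mask(pred, "pred"); truth <- as_mask(truth, "truth")
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    stopf("mask shapes differ")
  }
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  undefined <- character()
  rate <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  list(accuracy = rate(tp + tn, tp + tn + fp + fn, "accuracy"),
       f1 = rate(2 * tp, 2 * tp + fp + fn, "f1"),
       sensitivity = rate(tp, tp + fn, "sensitivity"),
       precision = rate(tp, tp + fp, "precision"),
       undefined = undefined)
}

per_class_metrics <- function(pred_vol, true_vol, class, spacing) {
  p <- pred_vol == class
  t <- true_vol == class
  cm <- confusion_metrics(p, t)
  list(dsc = dice_coefficient(p, t),
       hd95 = hausdorff95(p, t, spacing),
       accuracy = cm$accuracy, f1 = cm$f1,
       sensitivity = cm$sensitivity, precision = cm$precision)
}

#' Evaluate a model on a list of volumes
#'
#' Runs slice-wise 2D inference, stacks the per-slice predictions into a
#' 3D label volume per case, computes the six metrics per foreground
#' class, and averages over cases and then over classes.  A class absent
#' from a case's ground truth is excluded from that class's average; an
#' HD95 that is undefined (empty prediction) is excluded from the HD95
#' average and counted in `hd95_missing`.
#'
#' @param model a built (usually trained) `cpt_model`, or `NULL` when
#'   `predictions` are supplied.
#' @param volumes list of volumes as produced by
#'   [generate_phantom_volume()] (fields `slices`, `labels`, `spacing`).
#' @param predictions optional list of precomputed label volumes, used
#'   instead of running the model.
#' @return a `metric_report`: `per_class` data frame (one row per
#'   foreground class) and `average` (macro average over classes).
#' @export
evaluate_volumes <- function(model, volumes, predictions = NULL) {
  if (!length(volumes)) stopf("need at least one volume")
  n_classes <- max(vapply(volumes, function(v) max(v$labels), 0)) + 1L
  if (!is.null(model)) n_classes <- model$cfg$n_classes
  classes <- seq_len(n_classes - 1L)
  acc <- lapply(classes, function(c) list())
  for (i in seq_along(volumes)) {
    vol <- volumes[[i]]
    pred <- if (is.null(predictions)) infer_volume(model, vol) else predictions[[i]]
    for (cl in classes) {
      if (!any(vol$labels == cl)) next   # absent from ground truth
      acc[[cl]][[length(acc[[cl]]) + 1L]] <-
        per_class_metrics(pred, vol$labels, cl, vol$spacing)
    }
  }
  fields <- c("dsc", "hd95", "accuracy", "f1", "sensitivity", "precision")
  per_class <- data.frame(class = classes)
  for (f in fields) {
    per_class[[f]] <- vapply(classes, function(cl) {
      v <- vapply(acc[[cl]], `[[`, 0, f)
      if (!length(v)) return(NA_real_)
      mean(v, na.rm = TRUE)
    }, 0)
  }
  per_class$n_cases <- vapply(classes, function(cl) length(acc[[cl]]), 0L)
  per_class$hd95_missing <- vapply(classes, function(cl) {
    sum(is.na(vapply(acc[[cl]], `[[`, 0, "hd95")))
  }, 0L)
  avg <- lapply(fields, function(f) mean(per_class[[f]], na.rm = TRUE))
  names(avg) <- fields
  structure(list(per_class = per_class, average = avg), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Average over foreground classes: DSC %.4f, HD95 %.2f mm\n",
              x$average$dsc, x$average$hd95))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Write a metric report to JSON or CSV
#'
#' JSON carries the per-class table and the macro averages; CSV emits the
#' per-class table with the averages appended as a final `average` row.
#'
#' @param report a `metric_report`; @param path output file.
#' @param format `"json"` or `"csv"` (default inferred from the file
#'   extension).
#' @export
write_metric_report <- function(report, path,
                                format = if (grepl("\\.csv$", path)) "csv"
                                         else "json") {
  if (format == "json") {
    jsonlite::write_json(list(per_class = report$per_class,
                              average = report$average),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    tab <- report$per_class
    tab$class <- as.character(tab$class)
    avg <- data.frame(class = "average", report$average,
                      n_cases = NA_integer_, hd95_missing = NA_integer_)
    utils::write.csv(rbind(tab, avg), path, row.names = FALSE)
  }
  invisible(path)
}
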