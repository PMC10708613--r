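test_that("dice coefficient matches its closed form", {
  a <- array(FALSE, c(2, 4, 4)); b <- a
  a[1, 1:2, 1:2] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b[2, 3:4, 3:4] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = 4, |B| = 6, |A n B| = 3 -> 0.6
  a2 <- c(rep(TRUE, 4), rep(FALSE, 4))
  b2 <- c(rep(TRUE, 3), FALSE, rep(TRUE, 3), FALSE)
  expect_equal(dice_coefficient(a2, b2), 2 * 3 / (4 + 6))
  expect_equal(dice_coefficient(array(FALSE, c(2, 2)), array(FALSE, c(2, 2))), 1)
  expect_error(dice_coefficient(a, array(FALSE, c(2, 4, 5))), "differ")
  # symmetry and monotonicity under a growing intersection
  expect_equal(dice_coefficient(a2, b2), dice_coefficient(b2, a2))
})

test_that("hd95 handles exact, anisotropic and empty cases", {
  m <- array(FALSE, c(3, 6, 6))
  m[2, 2:4, 2:4] <- TRUE
  expect_equal(hausdorff95(m, m, c(3, 1, 1)), 0)
  # two single voxels 5 mm apart under isotropic spacing
  a <- array(FALSE, c(1, 8, 8)); b <- a
  a[1, 2, 2] <- TRUE; b[1, 2, 7] <- TRUE
  expect_equal(hausdorff95(a, b, c(1, 1, 1)), 5)
  # anisotropic: one-slice offset at 3 mm pitch
  a3 <- array(FALSE, c(2, 4, 4)); b3 <- a3
  a3[1, 2, 2] <- TRUE; b3[2, 2, 2] <- TRUE
  expect_equal(hausdorff95(a3, b3, c(3, 1, 1)), 3)
  expect_true(is.na(hausdorff95(a3, array(FALSE, c(2, 4, 4)), c(3, 1, 1))))
  # printed sum form on request
  expect_equal(hausdorff95(a, b, c(1, 1, 1), combine = "sum"), 10)
})

test_that("hd95 matches the all-pairs brute-force oracle", {
  set.seed(15)
  for (i in 1:25) {
    a <- array(runif(4 * 6 * 6) < 0.25, c(4, 6, 6))
    b <- array(runif(4 * 6 * 6) < 0.25, c(4, 6, 6))
    if (!any(a) || !any(b)) next
    sp <- c(sample(c(1, 3), 1), 1, 1)
    expect_equal(hausdorff95(a, b, sp), oracle_hd95(a, b, sp),
                 tolerance = 1e-10)
    # hd95 never exceeds the exact (100th percentile) Hausdorff distance
    full <- max(max(cptseg:::nn_dist(cptseg:::mask_coords(a, sp),
                                     cptseg:::mask_coords(b, sp))),
                max(cptseg:::nn_dist(cptseg:::mask_coords(b, sp),
                                     cptseg:::mask_coords(a, sp))))
    expect_lte(hausdorff95(a, b, sp), full + 1e-12)
    # symmetry
    expect_equal(hausdorff95(a, b, sp), hausdorff95(b, a, sp))
  }
})

test_that("confusion metrics match the worked tally and counting oracle", {
  # TP=3, FP=1, FN=1, TN=5
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  truth <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$f1, 0.75)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "f1", "sensitivity",
                                "precision")]),
               c(accuracy = 1, f1 = 1, sensitivity = 1, precision = 1))
  # randomized cases vs an element-wise counting oracle; F1 equals the
  # harmonic mean of precision and recall whenever all are defined
  set.seed(16)
  for (i in 1:30) {
    p <- runif(50) < 0.4
    t <- runif(50) < 0.4
    cm <- confusion_metrics(p, t)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in 1:50) {
      if (p[j] && t[j]) tp <- tp + 1
      else if (p[j] && !t[j]) fp <- fp + 1
      else if (!p[j] && t[j]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(cm$accuracy, (tp + tn) / 50)
    expect_equal(cm$f1, if (2 * tp + fp + fn == 0) 0 else
      2 * tp / (2 * tp + fp + fn))
    if (!length(cm$undefined) && cm$precision + cm$sensitivity > 0) {
      expect_equal(cm$f1, 2 * cm$precision * cm$sensitivity /
                     (cm$precision + cm$sensitivity))
    }
  }
  # zero-denominator flags
  cm0 <- confusion_metrics(rep(FALSE, 4), rep(FALSE, 4))
  expect_true(all(c("f1", "sensitivity", "precision") %in% cm0$undefined))
})

test_that("volume evaluation aggregates per-organ metrics correctly", {
  spec <- phantom_spec(n_cases = 2, seed = 11)
  vols <- lapply(1:2, function(i) generate_phantom_volume(spec, i))
  # ground truth fed back as prediction: perfect scores for present classes
  rep <- evaluate_volumes(NULL, vols, predictions = lapply(vols, `[[`, "labels"))
  present <- rep$per_class$n_cases > 0
  expect_true(all(rep$per_class$dsc[present] == 1))
  expect_true(all(rep$per_class$hd95[present] == 0))
  expect_equal(rep$average$dsc, 1)
  # all-background predictions: DSC 0 for present classes, HD95 missing
  zero <- lapply(vols, function(v) array(0L, dim(v$labels)))
  rep0 <- evaluate_volumes(NULL, vols, predictions = zero)
  expect_true(all(rep0$per_class$dsc[present] == 0))
  expect_true(all(rep0$per_class$hd95_missing[present] ==
                    rep0$per_class$n_cases[present]))
  # analytic check for one organ against direct per-class computation
  cl <- which(present)[1]
  direct <- mean(vapply(vols, function(v) {
    dice_coefficient(v$labels == cl, v$labels == cl)
  }, 0))
  expect_equal(rep$per_class$dsc[cl], direct)
})

test_that("metric reports serialize to JSON and CSV", {
  spec <- phantom_spec(n_cases = 1, slices_per_case = 2, seed = 33)
  vol <- generate_phantom_volume(spec, 1)
  rep <- evaluate_volumes(NULL, list(vol), predictions = list(vol$labels))
  pj <- tempfile(fileext = ".json"); pc <- tempfile(fileext = ".csv")
  write_metric_report(rep, pj)
  write_metric_report(rep, pc)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(back$average$dsc, rep$average$dsc)
  tab <- read.csv(pc)
  expect_equal(nrow(tab), 9)                 # 8 classes + average row
  expect_equal(tab$dsc[tab$class == "average"], rep$average$dsc)
  unlink(c(pj, pc))
})
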