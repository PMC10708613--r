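## Seeded phantom generator: 8 ellipsoidal "organs" plus background in a
## stack of 2D slices, mimicking the cases -> slices -> multi-organ-label
## structure of abdominal CT segmentation sets.  Geometry is structural,
## not anatomical: fixed per-class position/size/intensity priors with a
## small per-case jitter.

## per-class priors in normalized volume coordinates (row, col, slice in
## [0,1]); intensities are distinct so a segmentation model can succeed
## from contrast alone
phantom_priors <- function() {
  data.frame(
    class = 1:8,
    organ = c("aorta", "gallbladder", "left_kidney", "right_kidney",
              "liver", "pancreas", "spleen", "stomach"),
    cr = c(0.38, 0.34, 0.62, 0.62, 0.32, 0.52, 0.50, 0.56),
    cc = c(0.50, 0.66, 0.70, 0.30, 0.30, 0.50, 0.82, 0.62),
    cs = c(0.50, 0.45, 0.55, 0.55, 0.40, 0.50, 0.45, 0.55),
    ar = c(0.050, 0.060, 0.090, 0.090, 0.200, 0.060, 0.110, 0.120),
    ac = c(0.050, 0.055, 0.075, 0.075, 0.180, 0.160, 0.075, 0.110),
    as = c(0.420, 0.220, 0.280, 0.280, 0.350, 0.250, 0.280, 0.300),
    intensity = c(0.90, 0.30, 0.55, 0.60, 0.45, 0.70, 0.50, 0.80))
}

#' Phantom dataset specification
#'
#' @param n_cases number of cases; @param slices_per_case slices per case.
#' @param image_size slice side length (>= 64 so the geometry priors are
#'   representable).
#' @param n_classes background + organ classes (9).
#' @param noise_std additive Gaussian intensity noise (sd, intensity
#'   units); 0 gives piecewise-constant intensities.
#' @param spacing physical voxel size (row, col, slice) in mm; the 3 mm
#'   slice pitch exercises anisotropic HD95.
#' @param jitter per-case relative jitter of organ centres and axes.
#' @param seed master seed; each case derives its own stream from it.
#' @export
phantom_spec <- function(n_cases = 6L, slices_per_case = 8L,
                         image_size = 64L, n_classes = 9L,
                         noise_std = 0.03, spacing = c(1, 1, 3),
                         jitter = 0.04, seed = 1L) {
  if (image_size < 64L) stopf("image_size below 64 cannot represent the geometry priors")
  if (n_classes != 9L) stopf("the phantom defines 8 organ classes + background")
  if (noise_std < 0) stopf("noise_std must be >= 0")
  structure(list(n_cases = as.integer(n_cases),
                 slices_per_case = as.integer(slices_per_case),
                 image_size = as.integer(image_size),
                 n_classes = 9L, noise_std = noise_std,
                 spacing = spacing, jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom volume
#'
#' Deterministic in `(spec$seed, case_index)`.  Organs are 3D ellipsoids
#' sliced along the stack axis, painted in class order 1..8 into empty
#' (background) voxels only, so earlier classes are never overwritten.
#' Intensities lie in `[0, 1]`.
#'
#' @param spec a [phantom_spec()]; @param case_index positive integer.
#' @return a volume: list with `case_id`, `slices` and `labels`
#'   (`S x H x W` arrays), `spacing`.
#' @export
generate_phantom_volume <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$slices_per_case; H <- spec$image_size; W <- spec$image_size
  pri <- phantom_priors()
  with_seed(derive_seed(spec$seed, case_index), {
    labels <- array(0L, c(S, H, W))
    vol <- array(0.15, c(S, H, W))          # constant background
    r <- (seq_len(H) - 0.5) / H
    cc <- (seq_len(W) - 0.5) / W
    sl <- (seq_len(S) - 0.5) / S
    for (k in seq_len(nrow(pri))) {
      p <- pri[k, ]
      ctr <- c(p$cr, p$cc, p$cs) * (1 + stats::runif(3, -spec$jitter, spec$jitter))
      ax <- c(p$ar, p$ac, p$as) * stats::runif(3, 1 - spec$jitter, 1 + spec$jitter)
      ## squared normalized distance on the (slice, row, col) grid
      dr <- ((r - ctr[1]) / ax[1])^2
      dc <- ((cc - ctr[2]) / ax[2])^2
      ds <- ((sl - ctr[3]) / ax[3])^2
      inside <- outer(ds, outer(dr, dc, "+"), "+") <= 1   # S x H x W
      paint <- inside & labels == 0L
      labels[paint] <- p$class
      vol[paint] <- p$intensity
    }
    if (spec$noise_std > 0) {
      vol <- vol + stats::rnorm(length(vol), sd = spec$noise_std)
      vol <- pmin(pmax(vol, 0), 1)
    }
    ## volume spacing is stored in array-axis order (slice, row, col)
    list(case_id = sprintf("case%04d", case_index),
         slices = vol, labels = labels,
         spacing = spec$spacing[c(3L, 1L, 2L)])
  })
}

#' Generate a case-disjoint train/test phantom dataset
#'
#' @param spec a [phantom_spec()] (`n_cases >= 2`).
#' @param train_fraction fraction of cases assigned to training (the
#'   reference protocol's 18-of-30 split shape).
#' @return list with `train` and `test` volume lists and a `manifest`
#'   data frame recording case ids, derived seeds, split membership and
#'   the classes present per case.
#' @export
generate_dataset <- function(spec, train_fraction = 0.6) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_cases < 2L) stopf("need at least 2 cases to split")
  vols <- lapply(seq_len(spec$n_cases),
                 function(i) generate_phantom_volume(spec, i))
  n_train <- max(1L, min(spec$n_cases - 1L,
                         round(spec$n_cases * train_fraction)))
  idx_train <- seq_len(n_train)
  manifest <- data.frame(
    case_id = vapply(vols, `[[`, "", "case_id"),
    case_index = seq_len(spec$n_cases),
    seed = vapply(seq_len(spec$n_cases),
                  function(i) derive_seed(spec$seed, i), 0L),
    split = ifelse(seq_len(spec$n_cases) %in% idx_train, "train", "test"),
    classes = vapply(vols, function(v) {
      paste(sort(unique(as.integer(v$labels[v$labels > 0]))), collapse = ",")
    }, ""))
  list(train = vols[idx_train],
       test = vols[setdiff(seq_len(spec$n_cases), idx_train)],
       manifest = manifest)
}

## ---- fixture I/O -------------------------------------------------------

#' Write phantom volumes to disk
#'
#' Formats: `"nii.gz"` (one intensity + one label NIfTI pair per case,
#' spacing preserved), `"png"` (one 16-bit intensity and one 8-bit label
#' PNG per slice), or `"tsv"` (plain-text slice tables).  Labels round-trip
#' losslessly in every format; intensities up to format precision.
#'
#' @param volumes list of volumes; @param dir output directory.
#' @param format one of `"nii.gz"`, `"png"`, `"tsv"`.
#' @return invisibly, the written file paths.
#' @export
write_fixture <- function(volumes, dir, format = c("nii.gz", "png", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (vol in volumes) {
    S <- dim(vol$slices)[1L]
    if (format == "nii.gz") {
      ## NIfTI is (x, y, z): store as (H, W, S)
      img <- aperm(vol$slices, c(2L, 3L, 1L))
      lab <- aperm(vol$labels, c(2L, 3L, 1L))
      pi_ <- file.path(dir, paste0(vol$case_id, "_img.nii.gz"))
      pl <- file.path(dir, paste0(vol$case_id, "_lab.nii.gz"))
      sp <- vol$spacing[c(2L, 3L, 1L)]          # (row, col, slice)
      ref <- list(pixdim = c(-1, sp, 0, 0, 0, 0))
      RNifti::writeNifti(RNifti::asNifti(img, reference = ref), pi_)
      storage.mode(lab) <- "integer"
      RNifti::writeNifti(RNifti::asNifti(lab, reference = ref), pl,
                         datatype = "int16")
      paths <- c(paths, pi_, pl)
    } else if (format == "png") {
      for (s in seq_len(S)) {
        pi_ <- file.path(dir, sprintf("%s_s%03d_img.png", vol$case_id, s))
        pl <- file.path(dir, sprintf("%s_s%03d_lab.png", vol$case_id, s))
        png::writePNG(vol$slices[s, , ], pi_, dpi = NULL)
        png::writePNG(vol$labels[s, , ] / 255, pl)
        paths <- c(paths, pi_, pl)
      }
    } else {
      pi_ <- file.path(dir, paste0(vol$case_id, "_img.tsv"))
      pl <- file.path(dir, paste0(vol$case_id, "_lab.tsv"))
      hdr <- sprintf("# dims %d %d %d spacing %g %g %g", S,
                     dim(vol$slices)[2L], dim(vol$slices)[3L],
                     vol$spacing[1L], vol$spacing[2L], vol$spacing[3L])
      writeLines(c(hdr, apply(matrix(vol$slices, S), 1L, paste, collapse = "\t")), pi_)
      writeLines(c(hdr, apply(matrix(vol$labels, S), 1L, paste, collapse = "\t")), pl)
      paths <- c(paths, pi_, pl)
    }
  }
  invisible(paths)
}

#' Read phantom volumes written by [write_fixture()]
#' @param dir fixture directory; @param format the format written.
#' @export
read_fixture <- function(dir, format = c("nii.gz", "png", "tsv")) {
  format <- match.arg(format)
  if (format == "nii.gz") {
    imgs <- sort(list.files(dir, "_img\\.nii\\.gz$", full.names = TRUE))
    lapply(imgs, function(pi_) {
      pl <- sub("_img\\.nii\\.gz$", "_lab.nii.gz", pi_)
      img <- RNifti::readNifti(pi_)
      lab <- RNifti::readNifti(pl)
      sp <- as.numeric(RNifti::pixdim(img))     # (row, col, slice)
      list(case_id = sub("_img\\.nii\\.gz$", "", basename(pi_)),
           slices = aperm(array(as.numeric(img), dim(img)), c(3L, 1L, 2L)),
           labels = aperm(array(as.integer(lab), dim(lab)), c(3L, 1L, 2L)),
           spacing = sp[c(3L, 1L, 2L)])
    })
  } else if (format == "png") {
    imgs <- sort(list.files(dir, "_img\\.png$", full.names = TRUE))
    ids <- unique(sub("_s[0-9]+_img\\.png$", "", basename(imgs)))
    lapply(ids, function(id) {
      si <- sort(list.files(dir, paste0("^", id, "_s[0-9]+_img\\.png$"),
                            full.names = TRUE))
      sl <- sort(list.files(dir, paste0("^", id, "_s[0-9]+_lab\\.png$"),
                            full.names = TRUE))
      slices <- lapply(si, png::readPNG)
      labels <- lapply(sl, function(p) round(png::readPNG(p) * 255))
      S <- length(slices)
      H <- nrow(slices[[1L]]); W <- ncol(slices[[1L]])
      list(case_id = id,
           slices = aperm(array(unlist(slices), c(H, W, S)), c(3L, 1L, 2L)),
           labels = array(as.integer(aperm(array(unlist(labels), c(H, W, S)),
                                           c(3L, 1L, 2L))), c(S, H, W)),
           spacing = c(3, 1, 1))   # PNG carries no spacing; default pitch
    })
  } else {
    imgs <- sort(list.files(dir, "_img\\.tsv$", full.names = TRUE))
    lapply(imgs, function(pi_) {
      pl <- sub("_img\\.tsv$", "_lab.tsv", pi_)
      hdr <- strsplit(readLines(pi_, n = 1L), " ")[[1L]]
      dims <- as.integer(hdr[3:5]); sp <- as.numeric(hdr[7:9])
      rd <- function(p) {
        m <- as.matrix(utils::read.table(p, sep = "\t", skip = 1L))
        array(as.vector(m), dims)
      }
      slices <- rd(pi_)
      labels <- rd(pl)
      storage.mode(labels) <- "integer"
      list(case_id = sub("_img\\.tsv$", "", basename(pi_)),
           slices = slices, labels = labels, spacing = sp)
    })
  }
}
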