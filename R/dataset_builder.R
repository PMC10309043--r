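# Training-dataset construction from partially annotated EM sections.
#
# The pipeline: stretch the EM grayscale, find the saturated (fully
# annotated) region of the label image, rotate both images by a random
# angle, recompute the saturated region on the rotated labels, use the
# chessboard (Chebyshev) distance from labeled pixels to the nearest
# unlabeled pixel to find centers whose square patch is guaranteed fully
# annotated, crop registered EM/label patches there, and augment.

#' Grayscale stretch parameters
#'
#' Percentile anchors for contrast stretching. The anchors are fitted once
#' per source image ([fit_preprocess()]) and persisted with the dataset so
#' that inference applies the identical grayscale correction.
#'
#' @param low,high percentile anchors in `[0, 100]`, `low < high`.
#' @return A `preprocess_params` object; `low_val`/`high_val` hold fitted
#'   anchor gray values once [fit_preprocess()] has run.
#' @export
preprocess_params <- function(low = 1, high = 99) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stopf("stretch anchors need low < high, got %s / %s", low, high)
  structure(list(low_pct = low, high_pct = high, low_val = NULL, high_val = NULL),
            class = "preprocess_params")
}

#' Fit stretch anchors on an image
#'
#' @param params a [preprocess_params()].
#' @param image grayscale matrix on the 0..255 scale.
#' @return `params` with `low_val` and `high_val` set to the image's
#'   percentile gray values.
#' @export
fit_preprocess <- function(params, image) {
  q <- quantile(image, c(params$low_pct, params$high_pct) / 100, names = FALSE)
  params$low_val <- q[1L]
  params$high_val <- q[2L]
  params
}

#' Stretch an image's grayscale
#'
#' Pixels at or below the low anchor map to 0, at or above the high anchor
#' to 255, linearly in between. Unfitted params are fitted on the image
#' itself. Constant images are returned unchanged.
#'
#' @inheritParams fit_preprocess
#' @return Stretched grayscale matrix on 0..255.
#' @export
stretch_grayscale <- function(image, params = preprocess_params()) {
  if (is.null(params$low_val)) params <- fit_preprocess(params, image)
  lo <- params$low_val; hi <- params$high_val
  if (hi <= lo) return(image)
  clamp((image - lo) / (hi - lo), 0, 1) * 255
}

#' Mask of saturated (fully annotated) pixels
#'
#' @param labels integer label matrix.
#' @param unlabeled_value the id marking unannotated pixels.
#' @return Logical matrix, `TRUE` exactly where a label is present. The
#'   saturated region may have any shape.
#' @export
saturated_mask <- function(labels, unlabeled_value = EMSEG_UNLABELED) {
  labels != unlabeled_value
}

#' Chessboard distance to the nearest unlabeled pixel
#'
#' At each `TRUE` pixel, the Chebyshev (L-infinity) distance to the nearest
#' `FALSE` pixel; everything outside the image counts as unlabeled, and
#' `FALSE` pixels have distance 0.
#'
#' @param mask logical matrix (from [saturated_mask()]).
#' @return Integer distance matrix of the same shape.
#' @export
chessboard_distance <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_chessboard_distance(mask)
}

#' Pixels around which a fully annotated square patch fits
#'
#' Finds every pixel `c` such that the s x s axis-aligned patch centered
#' there (rows `c - floor((s-1)/2)` through `c + ceiling((s-1)/2)`)
#' contains only annotated pixels and lies wholly inside the image,
#' using the chessboard distance to the nearest unlabeled pixel. For odd
#' `s` the patch is the Chebyshev ball of radius `(s-1)/2`, so the exact
#' criterion is `distance >= ceiling(s/2)`. For even `s` the patch is the
#' radius-`s/2` neighbourhood of the 2 x 2 pixel block anchored at `c`,
#' so the exact criterion is that the minimum distance over that block is
#' at least `s/2`. Both directions hold: every returned center yields a
#' saturated patch, and every saturated centered patch is returned.
#'
#' @param mask logical saturation mask.
#' @param s patch side in pixels.
#' @return Two-column integer matrix of 1-based `(row, col)` centers
#'   (possibly zero rows).
#' @export
valid_patch_centers <- function(mask, s) {
  s <- check_count(s, "s")
  d <- chessboard_distance(mask)
  if (s %% 2L == 1L) return(which(d >= (s + 1L) %/% 2L, arr.ind = TRUE))
  h <- nrow(d); w <- ncol(d)
  if (h < 2L || w < 2L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  block_min <- pmin(d[-h, -w, drop = FALSE], d[-1L, -w, drop = FALSE],
                    d[-h, -1L, drop = FALSE], d[-1L, -1L, drop = FALSE])
  which(block_min >= s %/% 2L, arr.ind = TRUE)
}

patch_rows <- function(center, s) {
  (center - (s - 1L) %/% 2L):(center + s %/% 2L)
}

crop_patch <- function(img, center, s) {
  img[patch_rows(center[1L], s), patch_rows(center[2L], s), drop = FALSE]
}

#' Patch extraction configuration
#'
#' @param patch_size patch side in pixels; a positive multiple of 128 (the
#'   U-net's size granularity).
#' @param n_patches number of patches to draw.
#' @param rotate draw a continuous-uniform rotation angle in `[0, 360)`
#'   degrees for every patch.
#' @param augmentations subset of `c("flip", "gaussian_blur",
#'   "motion_blur", "histogram_equalize")`; each is applied independently
#'   with probability `augment_prob`.
#' @param augment_prob per-augmentation application probability.
#' @param n_classes 2 or 3 label classes.
#' @param unlabeled_value sentinel id for unannotated pixels.
#' @param val_fraction fraction of patches assigned to the validation split.
#' @param seed RNG seed; the dataset is a pure function of inputs + config.
#' @param max_retries angles to try before giving up on a draw.
#' @return A `patch_config` object.
#' @export
patch_config <- function(patch_size = 256L, n_patches = 100L, rotate = TRUE,
                         augmentations = character(), augment_prob = 0.5,
                         n_classes = 2L, unlabeled_value = EMSEG_UNLABELED,
                         val_fraction = 0.1, seed = 1L, max_retries = 25L) {
  patch_size <- check_mult128(patch_size, "patch_size")
  n_patches <- check_count(n_patches, "n_patches")
  check_flag(rotate, "rotate")
  bad <- setdiff(augmentations, EMSEG_AUGMENTATIONS)
  if (length(bad) > 0L)
    stopf("unknown augmentation(s): %s", paste(bad, collapse = ", "))
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  structure(list(patch_size = patch_size, n_patches = n_patches,
                 rotate = rotate, augmentations = augmentations,
                 augment_prob = augment_prob, n_classes = as.integer(n_classes),
                 unlabeled_value = as.integer(unlabeled_value),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 max_retries = check_count(max_retries, "max_retries")),
            class = "patch_config")
}

#' Supported photometric/geometric augmentations
#' @export
EMSEG_AUGMENTATIONS <- c("flip", "gaussian_blur", "motion_blur", "histogram_equalize")

# Rotate about the image center keeping the original footprint: rotate the
# full image (expanded canvas), then center-crop back.
rotate_about_center <- function(img, angle, filter = c("bilinear", "none"), bg = 0) {
  filter <- match.arg(filter)
  if (angle %% 360 == 0) return(img)
  r <- EBImage::imageData(EBImage::rotate(EBImage::Image(img), angle,
                                          filter = filter, bg.col = bg))
  h <- nrow(img); w <- ncol(img)
  y0 <- floor((nrow(r) - h) / 2); x0 <- floor((ncol(r) - w) / 2)
  r[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), drop = FALSE]
}

rotate_pair <- function(em, labels, angle, unlabeled_value) {
  if (angle %% 360 == 0) return(list(em = em, labels = labels))
  em_r <- rotate_about_center(em, angle, "bilinear", bg = 0)
  lab_r <- rotate_about_center(labels, angle, "none", bg = unlabeled_value)
  lab_r <- matrix(as.integer(round(lab_r)), nrow(lab_r), ncol(lab_r))
  list(em = em_r, labels = lab_r)
}

#' Apply one augmentation to a registered EM/label patch pair
#'
#' `flip` mirrors both images identically (axis drawn at random unless
#' given); the photometric operations (`gaussian_blur`, `motion_blur`,
#' `histogram_equalize`) perturb the EM patch only -- labels stay crisp
#' categorical. Unspecified parameters are drawn from the documented
#' defaults: Gaussian sigma uniform in `[0.5, 2]` px, motion-blur kernels
#' with odd length in `[3, 15]` px and uniform orientation.
#'
#' @param em grayscale patch (0..255).
#' @param labels integer label patch, same footprint.
#' @param op augmentation id, one of [EMSEG_AUGMENTATIONS].
#' @param params optional list of fixed parameters (`axis`, `sigma`,
#'   `length`, `angle`).
#' @return `list(em = , labels = )` with unchanged dimensions.
#' @export
augment_pair <- function(em, labels, op, params = list()) {
  switch(op,
    flip = {
      axis <- params$axis %||% sample(c("horizontal", "vertical"), 1L)
      if (axis == "horizontal") {
        em <- em[, rev(seq_len(ncol(em))), drop = FALSE]
        labels <- labels[, rev(seq_len(ncol(labels))), drop = FALSE]
      } else {
        em <- em[rev(seq_len(nrow(em))), , drop = FALSE]
        labels <- labels[rev(seq_len(nrow(labels))), , drop = FALSE]
      }
      list(em = em, labels = labels)
    },
    gaussian_blur = {
      sigma <- params$sigma %||% runif(1L, 0.5, 2)
      list(em = EBImage::imageData(EBImage::gblur(em / 255, sigma)) * 255,
           labels = labels)
    },
    motion_blur = {
      len <- params$length %||% sample(seq(3L, 15L, 2L), 1L)
      angle <- params$angle %||% runif(1L, 0, 180)
      k <- motion_kernel(len, angle)
      list(em = EBImage::imageData(EBImage::filter2(em, k, boundary = "replicate")),
           labels = labels)
    },
    histogram_equalize = {
      if (max(em) - min(em) < .Machine$double.eps) return(list(em = em, labels = labels))
      list(em = EBImage::imageData(EBImage::equalize(em / 255, range = c(0, 1),
                                                     levels = 256)) * 255,
           labels = labels)
    },
    stopf("unknown augmentation op: %s", op)
  )
}

# Linear motion-blur kernel: a unit-mass line of the given length and
# orientation rasterized on an odd-sized grid.
motion_kernel <- function(len, angle_deg) {
  if (len %% 2L == 0L) len <- len + 1L
  k <- matrix(0, len, len)
  c0 <- (len + 1L) / 2
  th <- angle_deg * pi / 180
  ts <- seq(-(len - 1) / 2, (len - 1) / 2, by = 0.25)
  for (t in ts) {
    i <- round(c0 + t * sin(th)); j <- round(c0 + t * cos(th))
    k[i, j] <- 1
  }
  k / sum(k)
}

#' Extract an augmented dataset of registered EM/label patches
#'
#' For each draw: sample a rotation angle, rotate the EM image (bilinear)
#' and the labels (nearest neighbour, rotation void filled with the
#' unlabeled sentinel) about the image center, recompute the saturated
#' mask and the chessboard-distance patch-center criterion on the rotated
#' labels, sample one valid center uniformly, crop the registered pair and
#' apply the configured augmentations. Every emitted label patch is
#' guaranteed saturated; the whole build is a pure function of
#' `(em, labels, cfg)`.
#'
#' @param em grayscale EM image (0..255 matrix); it is grayscale-stretched
#'   with `preprocess` before extraction.
#' @param labels integer label image registered to `em`.
#' @param cfg a [patch_config()].
#' @param preprocess a [preprocess_params()]; fitted on `em` if not already.
#' @param source name recorded in the per-patch manifest.
#' @return A `patch_dataset`: lists of EM and label patches, a manifest
#'   data frame (source, center, angle, augmentations, split), and the
#'   fitted preprocessing parameters.
#' @export
extract_patches <- function(em, labels, cfg = patch_config(),
                            preprocess = preprocess_params(),
                            source = "image") {
  if (!all(dim(em) == dim(labels)))
    stopf("em and labels must share the same footprint")
  if (is.null(preprocess$low_val)) preprocess <- fit_preprocess(preprocess, em)
  em <- stretch_grayscale(em, preprocess)
  s <- cfg$patch_size
  with_seed(cfg$seed, {
    ems <- vector("list", cfg$n_patches)
    labs <- vector("list", cfg$n_patches)
    man <- vector("list", cfg$n_patches)
    for (i in seq_len(cfg$n_patches)) {
      got <- FALSE
      for (try in seq_len(cfg$max_retries)) {
        angle <- if (cfg$rotate) runif(1L, 0, 360) else 0
        rot <- rotate_pair(em, labels, angle, cfg$unlabeled_value)
        centers <- valid_patch_centers(
          saturated_mask(rot$labels, cfg$unlabeled_value), s)
        if (nrow(centers) == 0L) next
        ct <- centers[sample.int(nrow(centers), 1L), ]
        ep <- crop_patch(rot$em, ct, s)
        lp <- crop_patch(rot$labels, ct, s)
        applied <- character()
        for (op in cfg$augmentations) {
          if (runif(1L) < cfg$augment_prob) {
            out <- augment_pair(ep, lp, op)
            ep <- out$em; lp <- out$labels
            applied <- c(applied, op)
          }
        }
        ems[[i]] <- ep
        labs[[i]] <- lp
        man[[i]] <- data.frame(patch = i, source = source, angle = angle,
                               center_row = ct[1L], center_col = ct[2L],
                               augmentations = paste(applied, collapse = "+"))
        got <- TRUE
        break
      }
      if (!got)
        stopf("insufficient saturated annotation for patch size %d (no valid center after %d angles)",
              s, cfg$max_retries)
    }
    manifest <- do.call(rbind, man)
    n_val <- round(cfg$val_fraction * cfg$n_patches)
    manifest$split <- "train"
    if (n_val > 0L)
      manifest$split[sample.int(cfg$n_patches, n_val)] <- "val"
    structure(list(em = ems, labels = labs, manifest = manifest,
                   preprocess = preprocess, config = cfg),
              class = "patch_dataset")
  })
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches of %d x %d px (%d classes), %d train / %d val\n",
              length(x$em), x$config$patch_size, x$config$patch_size,
              x$config$n_classes, sum(x$manifest$split == "train"),
              sum(x$manifest$split == "val")))
  invisible(x)
}

#' Per-class pixel frequencies of a patch dataset
#'
#' @param ds a `patch_dataset`.
#' @return Named numeric vector over class indices `0..n_classes-1`
#'   summing to 1 (unlabeled pixels never occur in a saturated dataset).
#' @export
class_frequencies <- function(ds) {
  counts <- numeric(ds$config$n_classes)
  for (lp in ds$labels) {
    t <- tabulate(lp + 1L, nbins = ds$config$n_classes)
    counts <- counts + t
  }
  p <- counts / sum(counts)
  names(p) <- as.character(seq_along(p) - 1L)
  p
}

#' Write a patch dataset to a directory
#'
#' Layout: `em/patch_%05d.png` (8-bit grayscale), `labels/patch_%05d.png`
#' (class-index grayscale) and `manifest.json` holding the per-patch
#' provenance, the fitted preprocessing parameters and the configuration.
#'
#' @param ds a `patch_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_patch_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$em)) {
    write_gray_png(ds$em[[i]], file.path(dir, "em", sprintf("patch_%05d.png", i)))
    write_class_png(ds$labels[[i]], file.path(dir, "labels", sprintf("patch_%05d.png", i)))
  }
  write_json_file(list(manifest = ds$manifest,
                       preprocess = unclass(ds$preprocess),
                       config = unclass(ds$config)),
                  file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a patch dataset written by [write_patch_dataset()]
#'
#' @param dir dataset directory.
#' @return A `patch_dataset`.
#' @export
read_patch_dataset <- function(dir) {
  meta <- read_json_file(file.path(dir, "manifest.json"))
  n <- nrow(meta$manifest)
  ems <- vector("list", n); labs <- vector("list", n)
  for (i in seq_len(n)) {
    ems[[i]] <- read_gray_png(file.path(dir, "em", sprintf("patch_%05d.png", i)))
    labs[[i]] <- read_class_png(file.path(dir, "labels", sprintf("patch_%05d.png", i)))
  }
  pp <- meta$preprocess; class(pp) <- "preprocess_params"
  cfg <- meta$config; class(cfg) <- "patch_config"
  structure(list(em = ems, labels = labs, manifest = meta$manifest,
                 preprocess = pp, config = cfg), class = "patch_dataset")
}
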