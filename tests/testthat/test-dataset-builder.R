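test_that("grayscale stretching maps anchors to 0/255 and is linear between", {
  img <- matrix(c(50, 125, 200, 60), 2, 2)
  pp <- fit_preprocess(preprocess_params(0, 100), img)
  out <- stretch_grayscale(img, pp)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 2], 255 * 10 / 150)
  expect_equal(out[1, 2], 255)
  # constant image unchanged
  const <- matrix(7, 3, 3)
  expect_equal(stretch_grayscale(const), const)
  # two-valued image with anchors at its values maps onto {0, 255}
  tv <- matrix(c(10, 20, 10, 20), 2, 2)
  expect_equal(stretch_grayscale(tv, fit_preprocess(preprocess_params(0, 100), tv)),
               matrix(c(0, 255, 0, 255), 2, 2))
})

test_that("saturated_mask marks exactly the labeled pixels", {
  full <- matrix(1L, 4, 4)
  expect_true(all(saturated_mask(full)))
  none <- matrix(EMSEG_UNLABELED, 4, 4)
  expect_false(any(saturated_mask(none)))
  checker <- matrix(c(1L, EMSEG_UNLABELED), 4, 4)
  expect_equal(saturated_mask(checker), checker != EMSEG_UNLABELED)
})

test_that("chessboard distance matches the exhaustive oracle", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(chessboard_distance(one)[3, 3], 1L)
  all3 <- matrix(TRUE, 3, 3)
  expect_equal(chessboard_distance(all3),
               matrix(c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L), 3, 3))
  set.seed(42)
  for (i in 1:30) {
    h <- sample(4:32, 1L); w <- sample(4:32, 1L)
    m <- matrix(runif(h * w) < runif(1, 0.3, 0.9), h, w)
    expect_identical(chessboard_distance(m), oracle_chessboard(m))
  }
})

test_that("valid patch centers guarantee fully annotated in-bounds patches", {
  # fully annotated 10x10, s = 4: brute force admits the 7x7 block of
  # centers whose 4x4 patch stays inside the image
  full <- matrix(TRUE, 10, 10)
  ct <- valid_patch_centers(full, 4L)
  brute <- which(matrix(vapply(seq_len(100L), function(t)
    oracle_patch_saturated(full, arrayInd(t, c(10L, 10L)), 4L), logical(1)),
    10L, 10L), arr.ind = TRUE)
  expect_equal(nrow(ct), nrow(brute))
  expect_equal(range(ct[, 1L]), c(2L, 8L))
  expect_equal(range(ct[, 2L]), c(2L, 8L))
  # the full image is itself a valid even-size patch
  ct128 <- valid_patch_centers(matrix(TRUE, 128L, 128L), 128L)
  expect_equal(nrow(ct128), 1L)
  expect_true(oracle_patch_saturated(matrix(TRUE, 128L, 128L), ct128[1L, ], 128L))
  # patch larger than the image: no centers
  expect_equal(nrow(valid_patch_centers(full, 40L)), 0L)
  # a 1-pixel hole excludes every center whose 2x2 patch would cover it
  holey <- matrix(TRUE, 12, 12); holey[6, 6] <- FALSE
  ct2 <- valid_patch_centers(holey, 2L)
  covering <- paste(c(5L, 5L, 6L, 6L), c(5L, 6L, 5L, 6L))
  expect_length(intersect(paste(ct2[, 1L], ct2[, 2L]), covering), 0L)
  expect_true(all(apply(ct2, 1L, function(c0) oracle_patch_saturated(holey, c0, 2L))))
  # every returned center passes the independent per-patch scan
  set.seed(9)
  for (i in 1:25) {
    m <- random_blob_mask(sample(16:40, 1L), sample(16:40, 1L))
    s <- sample(2:9, 1L)
    ct3 <- valid_patch_centers(m, s)
    if (nrow(ct3) == 0L) next
    ok <- apply(ct3, 1L, function(c0) oracle_patch_saturated(m, c0, s))
    expect_true(all(ok))
  }
  # the distance criterion is exact: it finds every valid center and
  # nothing else, for both parities of s
  for (i in 1:12) {
    m <- random_blob_mask(24, 24)
    s <- sample(2:8, 1L)
    got <- valid_patch_centers(m, s)
    want <- which(matrix(vapply(seq_len(24 * 24), function(t) {
      oracle_patch_saturated(m, arrayInd(t, c(24L, 24L)), s)
    }, logical(1)), 24L, 24L), arr.ind = TRUE)
    expect_equal(got[order(got[, 1L], got[, 2L]), , drop = FALSE],
                 want[order(want[, 1L], want[, 2L]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("extract_patches emits saturated, registered, reproducible patches", {
  fx <- generate_mosaic(mosaic_spec(size = 512, cells = 16, seed = 2))
  labels <- matrix(ifelse(fx$membrane, 1L, 0L), 512, 512)
  cfg <- patch_config(patch_size = 256L, n_patches = 10L, seed = 7L)
  ds <- extract_patches(fx$em, labels, cfg)
  expect_length(ds$em, 10L)
  for (i in 1:10) {
    expect_equal(dim(ds$em[[i]]), c(256L, 256L))
    expect_equal(dim(ds$labels[[i]]), c(256L, 256L))
    expect_false(any(ds$labels[[i]] == EMSEG_UNLABELED))
  }
  ds2 <- extract_patches(fx$em, labels, cfg)
  expect_identical(ds$em, ds2$em)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("without rotation a full-size patch is the (stretched) input", {
  fx <- generate_mosaic(mosaic_spec(size = 128, cells = 6, seed = 4))
  labels <- matrix(ifelse(fx$membrane, 1L, 0L), 128, 128)
  cfg <- patch_config(patch_size = 128L, n_patches = 1L, rotate = FALSE, seed = 1L)
  ds <- extract_patches(fx$em, labels, cfg)
  expect_equal(ds$em[[1L]], stretch_grayscale(fx$em, ds$preprocess), ignore_attr = TRUE)
  expect_equal(ds$labels[[1L]], labels, ignore_attr = TRUE)
})

test_that("too little saturated annotation raises an informative error", {
  em <- matrix(100, 160, 160)
  labels <- matrix(EMSEG_UNLABELED, 160, 160)
  labels[1:20, 1:20] <- 1L   # far too small for a 128 patch
  expect_error(
    extract_patches(em, labels, patch_config(patch_size = 128L, n_patches = 1L,
                                             max_retries = 3L)),
    "insufficient saturated annotation")
})

test_that("augmentations respect labels and degenerate inputs", {
  set.seed(3)
  em <- matrix(runif(64 * 64) * 255, 64, 64)
  lab <- matrix(sample(0:1, 64 * 64, TRUE), 64, 64)
  # double flip is the identity on both images
  f1 <- augment_pair(em, lab, "flip", list(axis = "horizontal"))
  f2 <- augment_pair(f1$em, f1$labels, "flip", list(axis = "horizontal"))
  expect_equal(f2$em, em)
  expect_equal(f2$labels, lab)
  # photometric ops leave labels bitwise unchanged
  for (op in c("gaussian_blur", "motion_blur", "histogram_equalize")) {
    out <- augment_pair(em, lab, op)
    expect_identical(out$labels, lab)
    expect_equal(dim(out$em), dim(em))
  }
  # equalizing a constant patch returns it unchanged
  const <- matrix(42, 32, 32)
  expect_equal(augment_pair(const, lab[1:32, 1:32], "histogram_equalize")$em, const)
  expect_error(augment_pair(em, lab, "posterize"), "unknown augmentation")
  expect_error(patch_config(augmentations = "posterize"), "unknown augmentation")
  expect_error(patch_config(patch_size = 100L), "multiple of 128")
})

test_that("datasets round-trip through disk and report class frequencies", {
  ds <- mosaic_dataset(n_patches = 4L, seed = 6L)
  p <- class_frequencies(ds)
  expect_equal(sum(p), 1)
  expect_length(p, 2L)
  dir <- withr::local_tempdir()
  write_patch_dataset(ds, dir)
  back <- read_patch_dataset(dir)
  expect_equal(length(back$em), length(ds$em))
  for (i in seq_along(ds$em)) {
    expect_lt(max(abs(back$em[[i]] - round(ds$em[[i]]))), 1e-9)
    expect_identical(back$labels[[i]], ds$labels[[i]])
  }
  expect_equal(back$config$patch_size, ds$config$patch_size)
})
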