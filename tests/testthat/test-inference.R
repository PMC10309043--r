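make_test_volume <- function(n_sections = 2L, size = 256L, tile = 128L, seed = 7L) {
  generate_volume(mosaic_spec(size = size, cells = 8L, seed = seed),
                  n_sections = n_sections, dir = withr::local_tempdir(.local_envir = parent.frame()),
                  drift = 2, tile_size = tile)
}

test_that("predict_block keeps registration, normalization and the 128 contract", {
  model <- tiny_unet(depth = 1L, base = 2L, seed = 4L)
  block <- array(runif(128 * 256 * 2) * 255, c(128L, 256L, 2L))
  prob <- predict_block(model, block)
  expect_equal(dim(prob), c(128L, 256L, 2L, 2L))
  sums <- apply(prob[, , , 1L], c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_error(predict_block(model, matrix(0, 100, 128)), "multiples of 128")
})

test_that("categorical_from_prob is an argmax with ties toward lower classes", {
  onehot <- array(0, c(2, 2, 3))
  onehot[, , 2] <- 1
  expect_true(all(categorical_from_prob(onehot) == 1L))
  uniform <- array(1 / 3, c(4, 4, 3))
  expect_true(all(categorical_from_prob(uniform) == 0L))
  set.seed(3)
  prob <- array(runif(6 * 5 * 3), c(6, 5, 3))
  got <- categorical_from_prob(prob)
  for (i in 1:6) for (j in 1:5) {
    expect_equal(got[i, j], which.max(prob[i, j, ]) - 1L)
  }
})

test_that("whole-volume prediction writes resolvable tiles and is resumable", {
  vols <- make_test_volume()
  model <- tiny_unet(depth = 1L, base = 2L, seed = 4L)
  out <- withr::local_tempdir()
  req <- prediction_request("whole", semantics = c("class", "prob"))
  res <- predict_volume(model, vols$em, req, out)
  # 2 sections x 4 tiles, for the class store and one probability store
  expect_length(list.files(file.path(out, "class"), pattern = "\\.png$",
                           recursive = TRUE), 8L)
  expect_length(list.files(file.path(out, "prob_c1"), pattern = "\\.png$",
                           recursive = TRUE), 8L)
  expect_true(file.exists(res$vsvi$class))
  d <- read_vsvi(res$vsvi$class)
  expect_equal(d$value_semantics, "class-index")
  # read-back reproduces the in-memory class maps exactly (evaluation is
  # per tile, so the direct computation uses the same tiling)
  cvol <- open_volume(file.path(out, "class"), "read")
  sec0 <- read_block(vols$em, list(z = c(0L, 1L), y = c(0L, 256L), x = c(0L, 256L)))[, , 1L]
  direct <- matrix(0L, 256L, 256L)
  for (rr in 0:1) for (cc in 0:1) {
    tile <- sec0[rr * 128 + 1:128, cc * 128 + 1:128]
    direct[rr * 128 + 1:128, cc * 128 + 1:128] <-
      categorical_from_prob(predict_block(model, tile)[, , , 1L])
  }
  expect_equal(read_block(cvol, list(z = c(0L, 1L), y = c(0L, 256L),
                                     x = c(0L, 256L)))[, , 1L],
               direct, ignore_attr = TRUE)
  # resume: nothing is rewritten
  req2 <- prediction_request("whole", semantics = c("class", "prob"), resume = TRUE)
  res2 <- predict_volume(model, vols$em, req2, out)
  expect_equal(res2$tiles_written, 0L)
  # purity: a second run elsewhere produces bit-identical tiles
  out2 <- withr::local_tempdir()
  predict_volume(model, vols$em, req, out2)
  f1 <- sort(list.files(file.path(out, "class"), pattern = "png$", recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(out, "class", f), "raw", 1e6),
                     readBin(file.path(out2, "class", f), "raw", 1e6))
  }
})

test_that("box and anchor predictions agree exactly with the whole-volume run", {
  vols <- make_test_volume()
  model <- tiny_unet(depth = 1L, base = 2L, seed = 4L)
  whole_dir <- withr::local_tempdir()
  predict_volume(model, vols$em, prediction_request("whole"), whole_dir)
  whole <- open_volume(file.path(whole_dir, "class"), "read")
  # box mode over a sub-roi
  box_dir <- withr::local_tempdir()
  roi <- list(z = c(0L, 2L), y = c(0L, 128L), x = c(128L, 256L))
  predict_volume(model, vols$em, prediction_request("box", roi = roi), box_dir)
  boxed <- open_volume(file.path(box_dir, "class"), "read")
  expect_equal(read_block(boxed, roi), read_block(whole, roi))
  # anchor mode crops the same tile-grid evaluation
  req <- prediction_request("anchors", anchors = matrix(c(128, 128, 1), 1L), cube = 128L)
  anch <- predict_anchors(model, vols$em, req)
  expect_length(anch, 1L)
  a <- anch[[1L]]
  # x/y cover the full cube; z is clipped to the volume's 2 sections
  expect_true(a$clipped)
  expect_equal(dim(a$prob)[1:2], c(128L, 128L))
  expect_equal(dim(a$prob)[4L], 2L)
  expect_equal(a$class, read_block(whole, a$roi), ignore_attr = TRUE)
  # a corner anchor is clipped and flagged
  reqc <- prediction_request("anchors", anchors = matrix(c(0, 0, 0), 1L), cube = 128L)
  corner <- predict_anchors(model, vols$em, reqc)[[1L]]
  expect_true(corner$clipped)
  expect_equal(dim(corner$prob)[1:2], c(64L, 64L))
  expect_equal(corner$class, read_block(whole, corner$roi), ignore_attr = TRUE)
  expect_error(prediction_request("anchors", anchors = matrix(numeric(0), 0L, 3L)),
               "non-empty")
  expect_error(prediction_request("box"), "roi")
})
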