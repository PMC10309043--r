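test_that("write_block / read_block round-trips grayscale and label voxels", {
  set.seed(11)
  for (dtype in c("gray8", "label24")) {
    root <- withr::local_tempdir()
    vol <- open_volume(root, "write", dims = c(3L, 300L, 260L),
                       tile_size = 128L, dtype = dtype)
    block <- if (dtype == "gray8") {
      array(sample(0:255, 300 * 260 * 3, TRUE), c(300L, 260L, 3L))
    } else {
      array(sample.int(70000L, 300 * 260 * 3, TRUE), c(300L, 260L, 3L))
    }
    write_block(vol, c(0L, 0L, 0L), block)
    back <- read_block(vol, list(z = c(0L, 3L), y = c(0L, 300L), x = c(0L, 260L)))
    expect_equal(unname(back), unname(block), ignore_attr = TRUE)
  }
})

test_that("edge tiles are zero-padded to the full tile size on disk", {
  root <- withr::local_tempdir()
  vol <- open_volume(root, "write", dims = c(1L, 100L, 100L), tile_size = 128L)
  write_block(vol, c(0L, 0L, 0L), matrix(200, 100L, 100L))
  files <- list.files(root, pattern = "\\.png$", recursive = TRUE, full.names = TRUE)
  expect_length(files, 1L)
  tile <- png::readPNG(files[1L])
  expect_equal(dim(tile), c(128L, 128L))
  expect_true(all(tile[101:128, ] == 0))
  expect_true(all(tile[1:100, 1:100] == 200 / 255))
})

test_that("descriptors validate, serialize and round-trip losslessly", {
  expect_error(vsvi_descriptor(c(1L, 512L, 512L), tile_size = 1000L),
               "tile_size.*multiple of 128")
  root <- withr::local_tempdir()
  vol <- open_volume(root, "write", dims = c(2L, 256L, 256L), tile_size = 128L)
  expect_error(write_vsvi(vol), "no tiles")
  write_block(vol, c(0L, 0L, 0L), matrix(7, 256L, 256L))
  out <- file.path(root, "preds.vsvi")
  d1 <- write_vsvi(vol, out)
  d2 <- read_vsvi(out)
  expect_equal(unclass(d1)[order(names(d1))], unclass(d2)[order(names(d2))],
               ignore_attr = TRUE)
  # emit -> parse -> emit is identity
  out2 <- file.path(root, "again.vsvi")
  write_json_file2 <- get("write_json_file", envir = asNamespace("emseg"))
  write_json_file2(unclass(d2), out2)
  expect_equal(unclass(read_vsvi(out2)), unclass(d2), ignore_attr = TRUE)
  # the url pattern resolves the first existing tile
  p <- file.path(root, sprintf(d2$source_url_pattern, 0L, 0L, 0L, 0L))
  expect_true(file.exists(p))
  # corrupt descriptor names the problem
  writeLines("{not json", out2)
  expect_error(read_vsvi(out2), "corrupt")
  # missing descriptor
  expect_error(open_volume(file.path(root, "nope"), "read"), "descriptor")
})

test_that("a 3-section 2048x2048 volume has 4 tiles per section at mip 0", {
  root <- withr::local_tempdir()
  vol <- open_volume(root, "write", dims = c(3L, 2048L, 2048L), tile_size = 1024L)
  expect_equal(volume_dims(vol), c(3L, 2048L, 2048L))
  plan1 <- chunk_plan(vol, list(z = c(0L, 1L), y = c(0L, 2048L), x = c(0L, 2048L)),
                      spec = chunk_spec())
  expect_equal(nrow(plan1), 4L)  # ceiling(2048/1024)^2
  for (z in 0:2) write_block(vol, c(z, 0L, 0L), matrix(z * 10, 2048L, 2048L))
  expect_length(list.files(root, pattern = "\\.png$", recursive = TRUE), 12L)
})

test_that("chunked traversal uses 16-section chunks, z-innermost order", {
  root <- withr::local_tempdir()
  vol <- open_volume(root, "write", dims = c(33L, 2048L, 2048L), tile_size = 1024L)
  spec <- chunk_spec()
  expect_equal(spec$z_depth, 16L)
  # 33 sections over one tile footprint: 3 chunks of depth 16, 16, 1
  plan <- chunk_plan(vol, list(z = c(0L, 33L), y = c(0L, 1024L), x = c(0L, 1024L)),
                     spec = spec)
  expect_equal(plan$z1 - plan$z0, c(16L, 16L, 1L))
  # 2x2-tile footprint, 16 sections: 4 chunks
  plan2 <- chunk_plan(vol, list(z = c(0L, 16L), y = c(0L, 2048L), x = c(0L, 2048L)),
                      spec = spec)
  expect_equal(nrow(plan2), 4L)
  # z varies fastest, then x, then y
  plan3 <- chunk_plan(vol, list(z = c(0L, 33L), y = c(0L, 2048L), x = c(0L, 2048L)),
                      spec = spec)
  expect_equal(plan3$z0[1:3], c(0L, 16L, 32L))
  expect_equal(plan3$x0[1:6], c(0L, 0L, 0L, 1024L, 1024L, 1024L))
  expect_true(all(plan3$y0[1:6] == 0L))
})

test_that("chunks partition random rois exactly (no omission, no duplication)", {
  set.seed(5)
  root <- withr::local_tempdir()
  vol <- open_volume(root, "write", dims = c(5L, 300L, 270L), tile_size = 128L)
  truth <- array(sample(0:255, 5 * 300 * 270, TRUE), c(300L, 270L, 5L))
  for (z in 0:4) write_block(vol, c(z, 0L, 0L), truth[, , z + 1L])
  for (rep in 1:5) {
    z <- sort(sample(0:5, 2L)); if (z[1L] == z[2L]) z[2L] <- z[1L] + 1L
    y <- sort(sample(0:300, 2L)); if (y[1L] == y[2L]) y[2L] <- y[1L] + 1L
    x <- sort(sample(0:270, 2L)); if (x[1L] == x[2L]) x[2L] <- x[1L] + 1L
    roi <- list(z = z, y = y, x = x)
    chunks <- read_chunks(vol, roi, spec = chunk_spec(z_depth = 2L, tile = 128L))
    cover <- array(0L, c(y[2L] - y[1L], x[2L] - x[1L], z[2L] - z[1L]))
    rebuilt <- cover
    for (ch in chunks) {
      o <- ch$origin; d <- dim(ch$data)
      ry <- (o[2L] - y[1L] + 1L):(o[2L] - y[1L] + d[1L])
      rx <- (o[3L] - x[1L] + 1L):(o[3L] - x[1L] + d[2L])
      rz <- (o[1L] - z[1L] + 1L):(o[1L] - z[1L] + d[3L])
      cover[ry, rx, rz] <- cover[ry, rx, rz] + 1L
      rebuilt[ry, rx, rz] <- ch$data
    }
    expect_true(all(cover == 1L))
    expect_equal(rebuilt,
                 truth[(y[1L] + 1L):y[2L], (x[1L] + 1L):x[2L],
                       (z[1L] + 1L):z[2L], drop = FALSE],
                 ignore_attr = TRUE)
  }
  expect_error(read_block(vol, list(z = c(0L, 9L), y = c(0L, 10L), x = c(0L, 10L))),
               "exceeds")
})

test_that("mips are 2x2 means for grayscale and stride-2 subsamples for labels", {
  root <- withr::local_tempdir()
  vol <- open_volume(root, "write", dims = c(1L, 256L, 256L), tile_size = 128L)
  set.seed(3)
  sec <- matrix(sample(0:255, 256 * 256, TRUE), 256L, 256L)
  write_block(vol, c(0L, 0L, 0L), sec)
  vol <- build_mips(vol, 1L)
  m1 <- read_block(vol, mip = 1L)[, , 1L]
  expected <- (sec[seq(1, 256, 2), seq(1, 256, 2)] + sec[seq(2, 256, 2), seq(1, 256, 2)] +
               sec[seq(1, 256, 2), seq(2, 256, 2)] + sec[seq(2, 256, 2), seq(2, 256, 2)]) / 4
  expect_lt(max(abs(m1 - expected)), 0.5 + 1e-9)  # 8-bit quantization only
  expect_equal(volume_dims(vol, 1L), c(1L, 128L, 128L))

  lroot <- withr::local_tempdir()
  lvol <- open_volume(lroot, "write", dims = c(1L, 256L, 256L), tile_size = 128L,
                      dtype = "label24")
  lab <- matrix(sample.int(500L, 256 * 256, TRUE), 256L, 256L)
  write_block(lvol, c(0L, 0L, 0L), lab)
  lvol <- build_mips(lvol, 1L)
  expect_equal(read_block(lvol, mip = 1L)[, , 1L],
               lab[seq(1, 256, 2), seq(1, 256, 2)], ignore_attr = TRUE)
})
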