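# Brute-force oracle for instance_to_membrane: an instance pixel is
# membrane iff some pixel within the Euclidean disk of radius r (outside
# the image counts) belongs to a different instance or to background.
oracle_membrane <- function(instances, r) {
  h <- nrow(instances); w <- ncol(instances)
  out <- matrix(FALSE, h, w)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  for (i in seq_len(h)) for (j in seq_len(w)) {
    id <- instances[i, j]
    if (id == 0L) next
    for (t in seq_len(nrow(off))) {
      ni <- i + off$di[t]; nj <- j + off$dj[t]
      if (ni < 1L || nj < 1L || ni > h || nj > w || instances[ni, nj] != id) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

test_that("instance erosion produces membrane bands matching the per-pixel oracle", {
  set.seed(8)
  for (rep in 1:4) {
    fx <- generate_mosaic(mosaic_spec(size = 48, cells = 5, seed = rep))
    for (r in 1:2) {
      cls <- instance_to_membrane(fx$instances, membrane_params(radius = r),
                                  class_scheme(3L))
      expect_equal(cls == 1L, oracle_membrane(fx$instances, r))
      # partition: every pixel gets exactly one class of the scheme
      expect_true(all(cls %in% c(0L, 1L, 2L)))
    }
  }
})

test_that("two abutting half-planes get a 2r-wide membrane band", {
  inst <- matrix(1L, 40, 40)
  inst[, 21:40] <- 2L
  for (r in 1:3) {
    cls <- instance_to_membrane(inst, membrane_params(radius = r), class_scheme(3L))
    mid <- cls[20, ]  # row away from the frame
    band <- which(mid == 1L)
    band <- band[band > r & band <= 40 - r]  # exclude the image-border frame
    expect_equal(band, (21L - r):(20L + r))
  }
})

test_that("a single instance filling the image gets a 1-pixel frame at r = 1", {
  inst <- matrix(1L, 9, 9)
  cls <- instance_to_membrane(inst, membrane_params(radius = 1L), class_scheme(3L))
  frame <- matrix(FALSE, 9, 9)
  frame[c(1L, 9L), ] <- TRUE; frame[, c(1L, 9L)] <- TRUE
  expect_equal(cls == 1L, frame)
  expect_true(all(cls[!frame] == 0L))
})

test_that("background handling follows the class scheme and fill_ecs", {
  inst <- matrix(0L, 12, 12)
  inst[2:5, 2:5] <- 1L
  inst[2:5, 8:11] <- 2L
  # 3-class, fill_ecs: background near two instances becomes membrane,
  # the rest becomes "other"
  cls <- suppressWarnings(  # r = 2 consumes the small 4x4 instances entirely
    instance_to_membrane(inst, membrane_params(radius = 2L, fill_ecs = TRUE),
                         class_scheme(3L)))
  expect_true(any(cls == 2L))
  expect_true(any(cls[, 6:7] == 1L))
  # 2-class, fill_ecs: all background is membrane
  cls2 <- instance_to_membrane(inst, membrane_params(radius = 1L, fill_ecs = TRUE),
                               class_scheme(2L))
  expect_true(all(cls2[inst == 0L] == 1L))
  # empty map at r = 1: all background class ("other" under 3 classes)
  empty <- matrix(0L, 6, 6)
  expect_true(all(instance_to_membrane(empty, membrane_params(1L),
                                       class_scheme(3L)) == 2L))
  expect_error(membrane_params(radius = 0L), "radius")
  # an instance consumed by erosion warns and becomes pure membrane
  tiny <- matrix(0L, 8, 8); tiny[4:5, 4:5] <- 1L
  w <- capture_warnings(out <- instance_to_membrane(tiny, membrane_params(radius = 3L),
                                                    class_scheme(3L)))
  expect_match(w, "vanished", all = TRUE)
  expect_true(all(out[tiny == 1L] == 1L))
})

test_that("skeletonization thins to one pixel preserving connectivity", {
  cc8 <- function(m) max(emseg:::cpp_cc_label(m, 8L))
  # empty mask -> empty skeleton
  expect_false(any(membrane_to_skeleton(matrix(FALSE, 8, 8))))
  # 1-pixel line is already thin
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_equal(membrane_to_skeleton(line), line)
  # filled disk: connected skeleton, nowhere 2x2 thick
  disk <- matrix(FALSE, 9, 9)
  for (i in 1:9) for (j in 1:9) if ((i - 5)^2 + (j - 5)^2 <= 16) disk[i, j] <- TRUE
  sk <- membrane_to_skeleton(disk)
  expect_true(any(sk))
  expect_true(all(sk[!disk] == FALSE))  # skeleton subset of mask
  expect_equal(cc8(sk), 1L)
  thick <- sk[1:8, 1:8] & sk[2:9, 1:8] & sk[1:8, 2:9] & sk[2:9, 2:9]
  expect_false(any(thick))
  # idempotence and component preservation on random blobs
  set.seed(12)
  for (rep in 1:5) {
    m <- random_blob_mask(24, 24, p_rect = 4L, p_holes = 0L)
    sk1 <- membrane_to_skeleton(m)
    expect_equal(cc8(sk1), cc8(m))
    expect_equal(membrane_to_skeleton(sk1), sk1)
  }
})

test_that("class mapping is surjective, conservative and flags unmapped ids", {
  labels <- matrix(c(10L, 20L, 30L, EMSEG_UNLABELED), 4, 4)
  sch <- class_scheme(3L, map = c("10" = 0L, "20" = 1L, "30" = 2L))
  out <- map_classes(labels, sch)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L, 2L, EMSEG_UNLABELED))
  # pixel-count conservation under a 2-class collapse (other -> membrane)
  sch2 <- class_scheme(2L, map = c("10" = 0L, "20" = 1L, "30" = 1L))
  out2 <- map_classes(labels, sch2)
  expect_equal(sum(out2 == 1L), sum(labels %in% c(20L, 30L)))
  expect_equal(sum(out2 == 0L), sum(labels == 10L))
  # identity scheme
  id <- matrix(c(0L, 1L, 2L), 3, 3)
  expect_equal(map_classes(id, class_scheme(3L, map = c("0" = 0L, "1" = 1L, "2" = 2L))), id)
  expect_error(map_classes(labels, class_scheme(3L, map = c("10" = 0L))), "20, 30")
})
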