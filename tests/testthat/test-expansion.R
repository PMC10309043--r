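test_that("watershed expansion handles the degenerate landscapes", {
  # no barriers: a single instance covers the image
  flat <- matrix(0, 20, 20)
  lab <- expand_watershed(flat, expansion_params())
  expect_equal(unique(as.vector(lab)), 1L)
  # all-membrane: empty instance map, not an error
  wall <- matrix(1, 20, 20)
  expect_true(all(expand_watershed(wall, expansion_params()) == 0L))
  expect_error(expand_watershed(matrix(2, 4, 4), expansion_params()), "\\[0, 1\\]")
})

test_that("a closed ring yields exactly two instances (inside and outside)", {
  prob <- matrix(0, 24, 24)
  prob[8:16, c(8L, 16L)] <- 1
  prob[c(8L, 16L), 8:16] <- 1
  lab <- expand_watershed(prob, expansion_params())
  ids <- setdiff(unique(as.vector(lab)), 0L)
  expect_length(ids, 2L)
  # oracle: connected components of the complement of the ring
  comp <- emseg:::cpp_cc_label(prob == 0, 8L)
  inside <- comp[12, 12]; outside <- comp[1, 1]
  expect_false(inside == outside)
  expect_equal(length(unique(lab[comp == inside])), 1L)
  expect_equal(length(unique(lab[comp == outside])), 1L)
  expect_false(lab[12, 12] == lab[1, 1])
})

test_that("watershed instances partition the non-ridge support connectedly", {
  set.seed(2)
  fx <- generate_mosaic(mosaic_spec(size = 96, cells = 8, seed = 13))
  prob <- matrix(ifelse(fx$membrane, 1, 0), 96, 96)
  lab <- expand_watershed(prob, expansion_params())
  expect_equal(max(lab), 8L)  # instance count equals ground-truth cell count
  for (id in seq_len(max(lab))) {
    expect_equal(max(emseg:::cpp_cc_label(lab == id, 8L)), 1L)
  }
  vi <- variation_of_information(fx$instances, lab)
  expect_lt(vi$vi, 0.1)
})

test_that("small instances merge into their lowest-barrier neighbour", {
  prob <- matrix(0, 16, 16)
  prob[, 8] <- 0.9        # strong wall splitting left from right
  prob[4, 1:8] <- 0.55    # weaker wall cutting a small upper-left pocket
  lab0 <- expand_watershed(prob, expansion_params(min_area = 1L))
  expect_equal(max(lab0), 3L)
  lab <- expand_watershed(prob, expansion_params(min_area = 30L))
  expect_equal(max(unique(as.vector(lab))[unique(as.vector(lab)) > 0L] |> length()), 2L)
  areas <- tabulate(lab[lab > 0L])
  expect_true(all(areas[areas > 0L] >= 30L))
  # the pocket joined its low-barrier (0.55) neighbour, not the far basin
  expect_equal(lab[2, 2], lab[8, 2])
  expect_false(lab[2, 2] == lab[8, 12])
})

test_that("seeded fill expands to the predicted borders and leaks through gaps", {
  ring <- matrix(FALSE, 20, 20)
  ring[6:14, c(6L, 14L)] <- TRUE
  ring[c(6L, 14L), 6:14] <- TRUE
  fill <- seeded_fill(ring, c(10L, 10L))
  comp <- emseg:::cpp_cc_label(!ring, 8L)
  expect_equal(fill, comp == comp[10, 10])
  expect_false(fill[1, 1])
  # a 1-pixel gap lets the fill leak outside: a merge error
  gap <- ring; gap[10, 6] <- FALSE
  leak <- seeded_fill(gap, c(10L, 10L))
  expect_true(leak[1, 1])
  # empty membrane mask: the fill covers the whole image
  expect_true(all(seeded_fill(matrix(FALSE, 5, 5), c(3L, 3L))))
  expect_error(seeded_fill(ring, c(6L, 6L)), "membrane")
})

test_that("variation of information matches closed forms and the oracle", {
  a <- matrix(rep(1:4, each = 25), 10, 10)
  expect_equal(variation_of_information(a, a)$vi, 0)
  # one segment vs two equal halves: exactly 1 bit, all of it split error
  one <- matrix(1L, 10, 10)
  halves <- matrix(rep(c(1L, 2L), each = 50), 10, 10)
  v <- variation_of_information(one, halves)
  expect_equal(v$vi, 1)
  expect_equal(v$h_a_given_b, 0)
  expect_equal(v$h_b_given_a, 1)
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(sample.int(5L, 64, TRUE), 8, 8)
    y <- matrix(sample.int(4L, 64, TRUE), 8, 8)
    expect_equal(variation_of_information(x, y)$vi, oracle_vi(x, y))
    # symmetry and non-negativity
    expect_equal(variation_of_information(x, y)$vi, variation_of_information(y, x)$vi)
    expect_gte(variation_of_information(x, y)$vi, 0)
    # triangle inequality spot-check
    z <- matrix(sample.int(3L, 64, TRUE), 8, 8)
    expect_lte(variation_of_information(x, z)$vi,
               variation_of_information(x, y)$vi + variation_of_information(y, z)$vi + 1e-12)
  }
  # id-0 pixels are excluded; disjoint supports are an error
  expect_error(variation_of_information(matrix(c(1L, 0L), 2, 2),
                                        matrix(c(0L, 1L), 2, 2)),
               "disjoint")
})
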