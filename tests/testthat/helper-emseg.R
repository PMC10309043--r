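# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately avoid the code paths they check.

# O(n^2) chessboard-distance oracle: exhaustive minimum over all unlabeled
# pixels (image padded with an unlabeled ring so the border counts).
oracle_chessboard <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pm <- matrix(FALSE, h + 2L, w + 2L)
  pm[2:(h + 1L), 2:(w + 1L)] <- mask
  f <- which(!pm, arr.ind = TRUE)
  d <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      d[i, j] <- min(pmax(abs(f[, 1L] - (i + 1L)), abs(f[, 2L] - (j + 1L))))
    }
  }
  d
}

# Random blobby mask: union of random rectangles minus random holes.
random_blob_mask <- function(h, w, p_rect = 3L, p_holes = 2L) {
  m <- matrix(FALSE, h, w)
  for (r in seq_len(p_rect)) {
    y <- sort(sample.int(h, 2L)); x <- sort(sample.int(w, 2L))
    m[y[1L]:y[2L], x[1L]:x[2L]] <- TRUE
  }
  for (r in seq_len(p_holes)) {
    y <- sample.int(h, 1L); x <- sample.int(w, 1L)
    m[y, x] <- FALSE
  }
  m
}

# Does every pixel of the s x s patch centred at ct lie inside the image
# and carry a label? Direct scan, independent of the distance transform.
oracle_patch_saturated <- function(mask, ct, s) {
  rows <- (ct[1L] - (s - 1L) %/% 2L):(ct[1L] + s %/% 2L)
  cols <- (ct[2L] - (s - 1L) %/% 2L):(ct[2L] + s %/% 2L)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > nrow(mask) ||
      max(cols) > ncol(mask)) return(FALSE)
  all(mask[rows, cols])
}

# Double-loop entropy computation for the variation of information,
# independent of table()/marginals.
oracle_vi <- function(a, b) {
  valid <- a > 0L & b > 0L
  a <- a[valid]; b <- b[valid]
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  h_ab <- 0; h_a <- 0; h_b <- 0
  for (x in ua) {
    px <- sum(a == x) / n
    h_a <- h_a - px * log2(px)
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) h_ab <- h_ab - pxy * log2(pxy)
    }
  }
  for (y in ub) {
    py <- sum(b == y) / n
    h_b <- h_b - py * log2(py)
  }
  2 * h_ab - h_a - h_b
}

tiny_unet <- function(depth = 1L, base = 2L, n_classes = 2L, seed = 1L) {
  build_unet(unet_config(depth = depth, base_channels = base,
                         n_classes = n_classes), seed = seed)
}

# Small membrane/intracellular dataset from a fixture mosaic.
mosaic_dataset <- function(n_patches = 8L, seed = 1L, size = 256L,
                           patch_size = 128L, val_fraction = 0.1, ...) {
  fx <- generate_mosaic(mosaic_spec(size = size, cells = 10L, seed = seed))
  labels <- matrix(ifelse(fx$membrane, 1L, 0L), size, size)
  extract_patches(fx$em, labels,
                  patch_config(patch_size = patch_size, n_patches = n_patches,
                               seed = seed, val_fraction = val_fraction, ...))
}

flatten_params <- function(model) {
  unlist(lapply(model$params, function(p) c(as.vector(p$w), p$b)))
}
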