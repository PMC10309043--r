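# Expansion of semantic membrane predictions into per-section instance
# segmentations, plus variation-of-information scoring of instance maps.

#' Watershed expansion parameters
#'
#' @param threshold membrane-probability threshold in `[0, 1]` below which
#'   (after minima suppression) pixels can seed an instance.
#' @param h depth of the h-minima suppression applied to the probability
#'   landscape before seeding; shallow local minima (depth < `h`) do not
#'   spawn their own seeds.
#' @param min_area instances smaller than this (pixels) are merged into
#'   their lowest-barrier neighbour.
#' @param connectivity 4 or 8 (default 8, used throughout the package).
#' @return An `expansion_params` object.
#' @export
expansion_params <- function(threshold = 0.5, h = 0.1, min_area = 1L,
                             connectivity = 8L) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  if (h < 0) stopf("h must be >= 0")
  min_area <- check_count(min_area, "min_area")
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  structure(list(threshold = threshold, h = h, min_area = min_area,
                 connectivity = as.integer(connectivity)),
            class = "expansion_params")
}

#' Grow 2D instances from a membrane probability map
#'
#' Region growing based on the watershed transform: the h-minima-suppressed
#' probability landscape is thresholded, its connected sub-threshold
#' components become seeds, and the watershed floods the original
#' probability landscape from those seeds. Pixels where two basins meet
#' (watershed ridges) keep id 0, matching the paint-until-border semantics
#' of flood-fill annotation. Instances below `min_area` are merged into the
#' neighbouring instance with the lowest probability barrier.
#'
#' An all-membrane input yields an empty instance map (no seeds), not an
#' error; an all-zero landscape yields a single instance covering the
#' image.
#'
#' @param membrane_prob single-channel membrane probability matrix in
#'   `[0, 1]`.
#' @param params an [expansion_params()].
#' @return Integer instance-id matrix (0 = membrane ridge / no instance).
#' @export
expand_watershed <- function(membrane_prob, params = expansion_params()) {
  if (any(membrane_prob < 0) || any(membrane_prob > 1))
    stopf("membrane probabilities must lie in [0, 1]")
  f <- cpp_hmin_suppress(membrane_prob, params$h)
  seeds <- cpp_cc_label(f < params$threshold, params$connectivity)
  if (max(seeds) == 0L)
    return(matrix(0L, nrow(membrane_prob), ncol(membrane_prob)))
  lab <- cpp_watershed_seeded(membrane_prob, seeds, params$connectivity)
  if (params$min_area > 1L)
    lab <- merge_small_instances(lab, membrane_prob, params$min_area)
  lab
}

# Merge instances below min_area into the neighbour (within a 2-pixel
# Chebyshev reach, enough to cross a 1-pixel ridge) whose shared interface
# has the lowest minimum probability barrier; isolated specks drop to 0.
merge_small_instances <- function(lab, prob, min_area) {
  repeat {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas > 0L & areas < min_area)
    if (length(small) == 0L) return(lab)
    l <- small[1L]
    sel <- which(lab == l, arr.ind = TRUE)
    h <- nrow(lab); w <- ncol(lab)
    barrier <- c()
    for (t in seq_len(nrow(sel))) {
      i <- sel[t, 1L]; j <- sel[t, 2L]
      for (di in -2:2) for (dj in -2:2) {
        ni <- i + di; nj <- j + dj
        if (ni < 1L || nj < 1L || ni > h || nj > w) next
        m <- lab[ni, nj]
        if (m > 0L && m != l) {
          b <- max(prob[i, j], prob[ni, nj])
          if (is.null(barrier[as.character(m)]) || is.na(barrier[as.character(m)]) ||
              b < barrier[as.character(m)])
            barrier[as.character(m)] <- b
        }
      }
    }
    lab[lab == l] <- if (length(barrier) > 0L)
      as.integer(names(barrier)[which.min(barrier)]) else 0L
  }
}

#' Flood fill a non-membrane region from a seed
#'
#' The 8-connected component of non-membrane pixels containing the seed --
#' the single "drop of paint" expansion used for machine-learning-aided
#' annotation: the fill grows until it reaches the predicted borders. A
#' broken membrane makes the fill leak into the neighbouring cell,
#' reproducing the classic merge-error failure mode.
#'
#' @param membrane_mask logical membrane mask.
#' @param seed 1-based `c(row, col)` of the seed pixel; must not lie on
#'   the membrane.
#' @return Logical region mask.
#' @export
seeded_fill <- function(membrane_mask, seed) {
  m <- membrane_mask != 0
  storage.mode(m) <- "logical"
  if (m[seed[1L], seed[2L]])
    stopf("seed (%d, %d) lies on a membrane pixel", seed[1L], seed[2L])
  comp <- cpp_cc_label(!m, 8L)
  comp == comp[seed[1L], seed[2L]]
}

#' Variation of information between two instance segmentations
#'
#' `VI = H(A|B) + H(B|A)` in bits, computed from the pixel-wise
#' contingency table of the two maps. Pixels carrying id 0 (membrane
#' ridges / unsegmented) in either map are excluded from the contingency
#' table; this masking convention is the package's documented choice. The
#' two conditional entropies are returned separately: with A the reference,
#' `H(B|A)` counts split errors and `H(A|B)` merge errors.
#'
#' @param seg_a,seg_b integer instance maps with the same footprint.
#' @return `list(vi, h_a_given_b, h_b_given_a)` in bits.
#' @export
variation_of_information <- function(seg_a, seg_b) {
  if (!all(dim(seg_a) == dim(seg_b)))
    stopf("instance maps must share the same footprint")
  valid <- seg_a > 0L & seg_b > 0L
  if (!any(valid))
    stopf("instance maps have disjoint valid (id > 0) supports")
  a <- as.vector(seg_a[valid]); b <- as.vector(seg_b[valid])
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h_ab <- ent(as.vector(p))
  h_a <- ent(pa); h_b <- ent(pb)
  list(vi = (h_ab - h_b) + (h_ab - h_a),
       h_a_given_b = h_ab - h_b,
       h_b_given_a = h_ab - h_a)
}
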