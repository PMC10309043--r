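# Synthetic EM-like fixtures: Voronoi cell mosaics with exact paired
# ground truth, so every pipeline stage is testable without downloads.

#' Specification of a synthetic EM-like cell mosaic
#'
#' A Voronoi mosaic of cells with dark membrane bands, intracellular
#' texture noise and optical blur -- the minimal texture with cell-like
#' topology. The membrane ground truth is derived from the instance ground
#' truth through [instance_to_membrane()] (erosion radius
#' `ceiling(membrane_width / 2)`), so the two are mutually consistent by
#' construction.
#'
#' @param size image side in pixels.
#' @param cells number of cells (Voronoi seeds).
#' @param membrane_width nominal membrane band width in pixels.
#' @param gray_intra,gray_membrane mean gray levels (0..255) of
#'   intracellular space and membranes.
#' @param noise_sd per-pixel Gaussian texture noise, gray levels.
#' @param blur_sigma Gaussian blur applied to the rendered image, pixels.
#' @param gaps number of membrane breaks to inject (0 = intact membranes);
#'   each break deletes membrane pixels within a disk of radius
#'   `gap_length / 2` around a random membrane pixel, creating controlled
#'   merge-error conditions.
#' @param gap_length diameter of each injected break, pixels.
#' @param seed RNG seed; the generated triple is fully deterministic.
#' @return A `mosaic_spec` object.
#' @export
mosaic_spec <- function(size = 256L, cells = 12L, membrane_width = 3L,
                        gray_intra = 165, gray_membrane = 60,
                        noise_sd = 10, blur_sigma = 1,
                        gaps = 0L, gap_length = 8L, seed = 1L) {
  size <- check_count(size, "size", 16L)
  cells <- check_count(cells, "cells")
  membrane_width <- check_count(membrane_width, "membrane_width")
  structure(list(size = size, cells = cells, membrane_width = membrane_width,
                 gray_intra = gray_intra, gray_membrane = gray_membrane,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 gaps = as.integer(gaps), gap_length = as.integer(gap_length),
                 seed = as.integer(seed)),
            class = "mosaic_spec")
}

membrane_radius <- function(spec) as.integer(ceiling(spec$membrane_width / 2))

voronoi_instances <- function(centers, size) {
  pix_y <- rep(seq_len(size), times = size)
  pix_x <- rep(seq_len(size), each = size)
  d2 <- outer(pix_y, centers[, 1L], "-")^2 + outer(pix_x, centers[, 2L], "-")^2
  matrix(max.col(-d2, ties.method = "first"), size, size)
}

#' Generate a synthetic EM-like cell mosaic with paired ground truth
#'
#' @param spec a [mosaic_spec()].
#' @return List with pixel-registered components: `em` (grayscale matrix,
#'   0..255), `instances` (integer instance ground truth, every pixel a
#'   positive cell id), `membrane` (logical membrane ground truth), and
#'   `centers` (the Voronoi seeds). With `gaps = 0`,
#'   `membrane` equals the membrane class of
#'   `instance_to_membrane(instances)` at the matching radius, exactly.
#' @export
generate_mosaic <- function(spec = mosaic_spec()) {
  with_seed(spec$seed, {
    n <- spec$size
    centers <- cbind(runif(spec$cells, 1, n), runif(spec$cells, 1, n))
    instances <- voronoi_instances(centers, n)
    cls <- instance_to_membrane(instances,
                                membrane_params(radius = membrane_radius(spec),
                                                fill_ecs = TRUE),
                                class_scheme(2L))
    membrane <- cls == 1L
    if (spec$gaps > 0L) {
      mem_idx <- which(membrane)
      for (g in seq_len(spec$gaps)) {
        at <- arrayInd(mem_idx[sample.int(length(mem_idx), 1L)], dim(membrane))
        rr <- max(1L, spec$gap_length %/% 2L)
        hole <- matrix(FALSE, n, n); hole[at[1L], at[2L]] <- TRUE
        membrane[cpp_dilate_disk(hole, rr)] <- FALSE
      }
    }
    em <- matrix(spec$gray_intra, n, n)
    em[membrane] <- spec$gray_membrane
    em <- em + rnorm(n * n, sd = spec$noise_sd)
    if (spec$blur_sigma > 0)
      em <- EBImage::imageData(EBImage::gblur(em / 255, spec$blur_sigma)) * 255
    em <- clamp(em, 0, 255)
    list(em = em, instances = instances, membrane = membrane, centers = centers)
  })
}

#' Generate a synthetic multi-section EM volume with paired labels
#'
#' Per-section mosaics whose cell centers drift slowly and coherently
#' across z (each cell carries a fixed random velocity scaled by `drift`);
#' with `drift = 0` all sections are identical. The EM sections and the
#' instance ground truth are written through the tile store as a `gray8`
#' and a `label24` volume.
#'
#' @param spec a [mosaic_spec()].
#' @param n_sections number of z sections.
#' @param dir output directory; the EM volume is written under `em/`, the
#'   instance labels under `labels/`.
#' @param drift standard deviation of the per-cell, per-section center
#'   velocity in pixels.
#' @param tile_size tile side for the stores.
#' @return `list(em = , labels = )` of `tile_volume` handles.
#' @export
generate_volume <- function(spec = mosaic_spec(), n_sections = 3L,
                            dir = tempfile("emseg_vol_"), drift = 1,
                            tile_size = 1024L) {
  n_sections <- check_count(n_sections, "n_sections")
  em_vol <- open_volume(file.path(dir, "em"), "write",
                        dims = c(n_sections, spec$size, spec$size),
                        tile_size = tile_size, dtype = "gray8",
                        value_semantics = "intensity")
  lab_vol <- open_volume(file.path(dir, "labels"), "write",
                         dims = c(n_sections, spec$size, spec$size),
                         tile_size = tile_size, dtype = "label24",
                         value_semantics = "instance-id")
  base <- with_seed(spec$seed, {
    list(centers = cbind(runif(spec$cells, 1, spec$size),
                         runif(spec$cells, 1, spec$size)),
         vel = matrix(rnorm(spec$cells * 2L, sd = drift), ncol = 2L))
  })
  for (z in seq_len(n_sections) - 1L) {
    centers_z <- clamp(base$centers + z * base$vel, 1, spec$size)
    sec <- with_seed(spec$seed, {
      instances <- voronoi_instances(centers_z, spec$size)
      cls <- instance_to_membrane(instances,
                                  membrane_params(radius = membrane_radius(spec),
                                                  fill_ecs = TRUE),
                                  class_scheme(2L))
      em <- matrix(spec$gray_intra, spec$size, spec$size)
      em[cls == 1L] <- spec$gray_membrane
      em <- em + rnorm(spec$size^2, sd = spec$noise_sd)
      if (spec$blur_sigma > 0)
        em <- EBImage::imageData(EBImage::gblur(em / 255, spec$blur_sigma)) * 255
      list(em = clamp(em, 0, 255), instances = instances)
    })
    write_block(em_vol, c(z, 0L, 0L), sec$em)
    write_block(lab_vol, c(z, 0L, 0L), sec$instances)
  }
  write_vsvi(em_vol)
  write_vsvi(lab_vol)
  list(em = em_vol, labels = lab_vol)
}
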