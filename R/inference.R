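# Chunked tiled prediction over tile volumes: whole-volume, boxed-ROI and
# anchor-point modes. In every mode the network is evaluated on the
# volume's fixed tile grid (one full tile per section at a time, no
# overlap), so overlapping regions across modes agree bit-exactly and two
# identical runs produce identical tiles. Chunks of 16 sections by one
# tile footprint are processed at a time, so memory stays at one chunk
# plus the model.

#' Prediction request
#'
#' @param mode `"whole"` (full volume), `"box"` (a 3D roi) or `"anchors"`
#'   (cubes centered on listed coordinates).
#' @param roi (box mode) half-open `list(z = , y = , x = )` box at `mip`.
#' @param anchors (anchor mode) numeric matrix with columns x, y, z.
#' @param cube (anchor mode) cube side in pixels; a multiple of 128.
#' @param mip mip level to read; should match the resolution the network
#'   was trained at.
#' @param preprocess fitted [preprocess_params()] so inference applies the
#'   same grayscale correction as dataset construction.
#' @param semantics outputs to write: `"class"` (categorical tiles) and/or
#'   `"prob"` (per-class probability tiles, scaled 0..255).
#' @param prob_classes class indices whose probability maps are written
#'   (default: membrane class 1).
#' @param resume skip tiles whose output files already exist.
#' @param z_depth sections per chunk (default 16).
#' @return A `prediction_request` object.
#' @export
prediction_request <- function(mode = c("whole", "box", "anchors"), roi = NULL,
                               anchors = NULL, cube = 256L, mip = 0L,
                               preprocess = NULL, semantics = "class",
                               prob_classes = 1L, resume = FALSE,
                               z_depth = 16L) {
  mode <- match.arg(mode)
  if (mode == "box" && is.null(roi)) stopf("box mode needs a `roi`")
  if (mode != "box" && !is.null(roi)) stopf("`roi` is only valid in box mode")
  if (mode == "anchors") {
    if (is.null(anchors) || NROW(anchors) == 0L) stopf("anchor mode needs a non-empty anchor list")
    cube <- check_mult128(cube, "cube")
  } else if (!is.null(anchors)) {
    stopf("`anchors` is only valid in anchor mode")
  }
  if (!all(semantics %in% c("class", "prob"))) stopf("semantics must be in c(\"class\", \"prob\")")
  structure(list(mode = mode, roi = roi, anchors = anchors, cube = as.integer(cube),
                 mip = as.integer(mip), preprocess = preprocess,
                 semantics = semantics, prob_classes = as.integer(prob_classes),
                 resume = isTRUE(resume), z_depth = check_count(z_depth, "z_depth")),
            class = "prediction_request")
}

#' Predict class probabilities for an image block
#'
#' Applies the stored grayscale correction, then the model, to every
#' section of the block. Sides must be multiples of 128 (callers pad).
#'
#' @param model a `seg_model`.
#' @param block `[H, W]` matrix or `[H, W, Z]` grayscale array (0..255).
#' @param preprocess fitted [preprocess_params()] or `NULL`.
#' @return `[H, W, n_classes, Z]` probability array, normalized over
#'   classes at every pixel.
#' @export
predict_block <- function(model, block, preprocess = NULL) {
  if (length(dim(block)) == 2L) block <- array(block, c(dim(block), 1L))
  h <- dim(block)[1L]; w <- dim(block)[2L]; nz <- dim(block)[3L]
  if (h %% 128L != 0L || w %% 128L != 0L)
    stopf("block sides must be multiples of 128, got %d x %d", h, w)
  K <- model$config$n_classes
  out <- array(0, c(h, w, K, nz))
  for (z in seq_len(nz)) {
    sec <- block[, , z]
    if (!is.null(preprocess)) sec <- stretch_grayscale(sec, preprocess)
    out[, , , z] <- forward_unet(model, prep_input(sec))$prob
  }
  out
}

#' Collapse class probabilities to a categorical map
#'
#' Per-pixel argmax; ties break toward the lower class index.
#'
#' @param prob `[H, W, K]` or `[H, W, K, Z]` probability array.
#' @return Integer class-index matrix (or `[H, W, Z]` array).
#' @export
categorical_from_prob <- function(prob) {
  d <- dim(prob)
  if (length(d) == 4L) {
    out <- array(0L, d[c(1L, 2L, 4L)])
    for (z in seq_len(d[4L])) out[, , z] <- categorical_from_prob(prob[, , , z])
    return(out)
  }
  cls <- max.col(matrix(prob, ncol = d[3L]), ties.method = "first") - 1L
  matrix(as.integer(cls), d[1L], d[2L])
}

# Predict one full tile (zero-padded at volume edges) for one section.
# Caching keyed on (mip, z, row, col) keeps anchor mode from recomputing
# shared tiles.
predict_tile <- function(model, vol, mip, z, row, col, preprocess, cache = NULL) {
  key <- sprintf("m%d_z%d_r%d_c%d", mip, z, row, col)
  if (!is.null(cache) && exists(key, envir = cache)) return(get(key, envir = cache))
  tile <- read_tile(vol, mip, z, row, col)
  prob <- predict_block(model, tile, preprocess)[, , , 1L]
  if (!is.null(cache)) assign(key, prob, envir = cache)
  prob
}

prob_dir_name <- function(k) sprintf("prob_c%d", k)

#' Predict a volume (or boxed region) and write VAST-loadable tiles
#'
#' Traverses the requested region chunk by chunk (16 sections by one tile
#' footprint, z-innermost order), predicts each tile, and writes
#' categorical tiles (class indices) plus optional per-class probability
#' tiles (scaled to 0..255) as fixed-size PNGs, each output volume with
#' its own `.vsvi` descriptor. A `run.json` provenance record is written
#' alongside. With `resume = TRUE`, tiles whose files already exist are
#' skipped, so an interrupted run can be continued without rewriting.
#'
#' @param model a `seg_model`.
#' @param vol input grayscale `tile_volume`.
#' @param req a [prediction_request()] (whole or box mode).
#' @param out_dir output directory; the categorical volume is written
#'   under `class/`, probability volumes under `prob_c<k>/`.
#' @return List with the output volume handles, descriptor paths and the
#'   number of tiles written.
#' @export
predict_volume <- function(model, vol, req, out_dir) {
  stopifnot(inherits(req, "prediction_request"))
  if (req$mode == "anchors")
    stopf("use predict_anchors() for anchor-mode requests")
  dims <- volume_dims(vol, req$mip)
  roi <- normalize_roi(if (req$mode == "box") req$roi else NULL, dims)
  ts <- vol$desc$tile_size
  class_vol <- open_volume(file.path(out_dir, "class"), "write", dims = dims,
                           tile_size = ts, dtype = "gray8",
                           value_semantics = "class-index",
                           voxel_size_nm = vol$desc$voxel_size_nm)
  prob_vols <- list()
  if ("prob" %in% req$semantics) {
    for (k in req$prob_classes) {
      prob_vols[[as.character(k)]] <-
        open_volume(file.path(out_dir, prob_dir_name(k)), "write", dims = dims,
                    tile_size = ts, dtype = "gray8",
                    value_semantics = "probability-0-255",
                    voxel_size_nm = vol$desc$voxel_size_nm)
    }
  }
  rows <- seq.int(roi$y[1L] %/% ts, (roi$y[2L] - 1L) %/% ts)
  cols <- seq.int(roi$x[1L] %/% ts, (roi$x[2L] - 1L) %/% ts)
  zs <- seq.int(roi$z[1L], roi$z[2L] - 1L)
  zgroups <- split(zs, (zs - roi$z[1L]) %/% req$z_depth)
  written <- 0L
  for (rr in rows) {           # traversal: z innermost, then x, then y
    for (cc in cols) {
      for (zg in zgroups) {
        for (z in zg) {
          targets <- tile_path(class_vol, 0L, z, rr, cc)
          for (k in names(prob_vols))
            targets <- c(targets, tile_path(prob_vols[[k]], 0L, z, rr, cc))
          if (req$resume && all(file.exists(targets))) next
          prob <- predict_tile(model, vol, req$mip, z, rr, cc, req$preprocess)
          write_tile(class_vol, 0L, z, rr, cc, categorical_from_prob(prob))
          for (k in names(prob_vols)) {
            write_tile(prob_vols[[k]], 0L, z, rr, cc,
                       round(prob[, , as.integer(k) + 1L] * 255))
          }
          written <- written + length(targets)
        }
      }
    }
  }
  vsvi <- list(class = file.path(class_vol$root, "volume.vsvi"))
  write_vsvi(class_vol, vsvi$class)
  for (k in names(prob_vols)) {
    vsvi[[prob_dir_name(as.integer(k))]] <-
      file.path(prob_vols[[k]]$root, "volume.vsvi")
    write_vsvi(prob_vols[[k]], vsvi[[prob_dir_name(as.integer(k))]])
  }
  write_run_log(out_dir, "predict",
                list(mode = req$mode, mip = req$mip, roi = roi,
                     semantics = req$semantics, tiles_written = written))
  list(class_volume = class_vol, prob_volumes = prob_vols,
       vsvi = vsvi, tiles_written = written)
}

#' Predict locally around anchor points
#'
#' For each anchor, the cube of side `req$cube` (clipped at volume edges;
#' the clipped extent is flagged) centered on it is predicted by
#' evaluating the same volume-aligned tiles as whole-volume prediction and
#' cropping, so anchor-mode output is bit-identical to the corresponding
#' region of a whole-volume run. Results are written under per-anchor
#' subdirectories with a summary manifest.
#'
#' @param model a `seg_model`.
#' @param vol input grayscale `tile_volume`.
#' @param req a [prediction_request()] in anchor mode (anchors are
#'   `(x, y, z)` rows, 0-based voxel coordinates at `req$mip`).
#' @param out_dir output directory, one `anchor_###/` folder per anchor.
#' @return List of per-anchor results: `prob` array, `class` block,
#'   `roi`, and `clipped` flag.
#' @export
predict_anchors <- function(model, vol, req, out_dir = NULL) {
  stopifnot(inherits(req, "prediction_request"))
  if (req$mode != "anchors") stopf("request is not in anchor mode")
  anchors <- req$anchors
  if (is.null(dim(anchors))) anchors <- matrix(anchors, ncol = 3L, byrow = TRUE)
  dims <- volume_dims(vol, req$mip)
  ts <- vol$desc$tile_size
  half <- req$cube %/% 2L
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(anchors))
  for (a in seq_len(nrow(anchors))) {
    x <- anchors[a, 1L]; y <- anchors[a, 2L]; z <- anchors[a, 3L]
    want <- list(z = c(z - half, z + half), y = c(y - half, y + half),
                 x = c(x - half, x + half))
    roi <- list(z = c(max(0L, want$z[1L]), min(dims[1L], want$z[2L])),
                y = c(max(0L, want$y[1L]), min(dims[2L], want$y[2L])),
                x = c(max(0L, want$x[1L]), min(dims[3L], want$x[2L])))
    if (roi$z[2L] <= roi$z[1L] || roi$y[2L] <= roi$y[1L] || roi$x[2L] <= roi$x[1L])
      stopf("anchor %d (%g, %g, %g) lies outside the volume", a, x, y, z)
    clipped <- !identical(want, roi)
    h <- roi$y[2L] - roi$y[1L]; w <- roi$x[2L] - roi$x[1L]
    nz <- roi$z[2L] - roi$z[1L]
    prob <- array(0, c(h, w, model$config$n_classes, nz))
    rows <- seq.int(roi$y[1L] %/% ts, (roi$y[2L] - 1L) %/% ts)
    cols <- seq.int(roi$x[1L] %/% ts, (roi$x[2L] - 1L) %/% ts)
    for (k in seq_len(nz)) {
      zz <- roi$z[1L] + k - 1L
      for (rr in rows) {
        for (cc in cols) {
          tp <- predict_tile(model, vol, req$mip, zz, rr, cc, req$preprocess, cache)
          ty <- rr * ts; tx <- cc * ts
          y0 <- max(roi$y[1L], ty); y1 <- min(roi$y[2L], ty + ts)
          x0 <- max(roi$x[1L], tx); x1 <- min(roi$x[2L], tx + ts)
          prob[(y0 - roi$y[1L] + 1L):(y1 - roi$y[1L]),
               (x0 - roi$x[1L] + 1L):(x1 - roi$x[1L]), , k] <-
            tp[(y0 - ty + 1L):(y1 - ty), (x0 - tx + 1L):(x1 - tx), ]
        }
      }
    }
    cls <- categorical_from_prob(prob)
    if (!is.null(out_dir)) {
      adir <- file.path(out_dir, sprintf("anchor_%03d", a))
      for (k in seq_len(nz)) {
        write_class_png(if (nz == 1L) cls[, , drop = TRUE] else cls[, , k],
                        file.path(adir, sprintf("class_z%05d.png", roi$z[1L] + k - 1L)))
      }
      write_json_file(list(anchor = c(x = x, y = y, z = z), cube = req$cube,
                           roi = roi, clipped = clipped),
                      file.path(adir, "manifest.json"))
    }
    out[[a]] <- list(prob = prob, class = cls, roi = roi, clipped = clipped)
  }
  if (!is.null(out_dir))
    write_run_log(out_dir, "predict_anchors",
                  list(n_anchors = nrow(anchors), cube = req$cube, mip = req$mip))
  out
}

#' Read anchor points from a whitespace-separated text file
#'
#' One `x y z` triple per line (0-based voxel coordinates), the plain-text
#' massaging target for coordinates exported from annotation-tool
#' skeletons.
#'
#' @param path text file path.
#' @return Numeric matrix with columns x, y, z.
#' @export
read_anchors <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  if (ncol(m) != 3L) stopf("anchor file must have 3 columns: x y z")
  m
}
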