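# Filesystem-backed tile-pyramid volumes and their VSVI descriptors.
#
# A volume is a directory of fixed-size PNG tiles, one tile per
# (mip, section, row, column), plus a JSON-syntax descriptor with extension
# .vsvi declaring the naming scheme, extents and value semantics -- the
# text-file contract the VAST annotation tool uses to mount tiled image
# stacks. Coordinates are 0-based (z section, y row, x column) and regions
# of interest are half-open boxes.

DEFAULT_NAMING <- "mip%d/z%05d/r%03d_c%03d.png"
VSVI_FORMAT <- "emseg-vsvi-1"
VSVI_DTYPES <- c("gray8", "label24")
VSVI_SEMANTICS <- c("intensity", "class-index", "probability-0-255", "instance-id")

#' Create a VSVI descriptor
#'
#' The descriptor is the volume's metadata record: tile naming scheme with
#' z/row/col (and mip) placeholders, extents in voxels, voxel size, tile
#' size, available mip levels, pixel type and value semantics. It serializes
#' to a UTF-8 JSON text file (extension `.vsvi`) and round-trips losslessly.
#' The key set is this package's documented dialect of VAST's descriptor
#' syntax.
#'
#' @param volume_size integer `c(depth, height, width)` in voxels at mip 0.
#' @param tile_size tile side in pixels; must be a positive multiple of 128.
#' @param dtype `"gray8"` (8-bit grayscale PNG tiles) or `"label24"`
#'   (integer ids packed into 24-bit RGB PNG tiles).
#' @param voxel_size_nm numeric `c(z, y, x)` voxel size in nanometres.
#' @param mip_levels integer vector of stored downsampling exponents; mip
#'   `m` holds the image downsampled by `2^m` in x and y (z untouched).
#' @param value_semantics what tile values mean: `"intensity"`,
#'   `"class-index"`, `"probability-0-255"` or `"instance-id"`.
#' @param source_url_pattern `sprintf` pattern mapping
#'   `(mip, z, row, col)` to a tile path relative to the volume root.
#' @return A `vsvi_descriptor` object (named list).
#' @export
vsvi_descriptor <- function(volume_size,
                            tile_size = 1024L,
                            dtype = "gray8",
                            voxel_size_nm = c(30, 4, 4),
                            mip_levels = 0L,
                            value_semantics = "intensity",
                            source_url_pattern = DEFAULT_NAMING) {
  desc <- structure(list(
    format = VSVI_FORMAT,
    source_url_pattern = source_url_pattern,
    tile_size = as.integer(tile_size),
    volume_size = as.integer(volume_size),
    voxel_size_nm = as.numeric(voxel_size_nm),
    mip_levels = sort(unique(as.integer(mip_levels))),
    dtype = dtype,
    value_semantics = value_semantics
  ), class = "vsvi_descriptor")
  validate_vsvi(desc)
  desc
}

#' Validate a VSVI descriptor
#'
#' Checks the descriptor's field set and invariants; errors name the
#' offending field.
#' @param desc a `vsvi_descriptor` or plain list parsed from a `.vsvi` file.
#' @return The descriptor, invisibly, with canonical types.
#' @export
validate_vsvi <- function(desc) {
  required <- c("source_url_pattern", "tile_size", "volume_size", "dtype")
  missing <- setdiff(required, names(desc))
  if (length(missing) > 0L)
    stopf("invalid .vsvi descriptor: missing field(s) %s",
          paste(sQuote(missing), collapse = ", "))
  if (!is.numeric(desc$tile_size) || length(desc$tile_size) != 1L ||
      desc$tile_size < 128 || desc$tile_size %% 128 != 0)
    stopf("invalid .vsvi descriptor: field 'tile_size' must be a positive multiple of 128, got %s",
          paste(desc$tile_size, collapse = ","))
  if (!is.numeric(desc$volume_size) || length(desc$volume_size) != 3L ||
      any(desc$volume_size < 1))
    stopf("invalid .vsvi descriptor: field 'volume_size' must be 3 positive voxel counts (depth, height, width)")
  if (!desc$dtype %in% VSVI_DTYPES)
    stopf("invalid .vsvi descriptor: field 'dtype' must be one of %s",
          paste(VSVI_DTYPES, collapse = ", "))
  if (!is.null(desc$value_semantics) && !desc$value_semantics %in% VSVI_SEMANTICS)
    stopf("invalid .vsvi descriptor: field 'value_semantics' must be one of %s",
          paste(VSVI_SEMANTICS, collapse = ", "))
  ok <- tryCatch({
    p <- sprintf(desc$source_url_pattern, 0L, 0L, 0L, 0L)
    is.character(p) && nzchar(p)
  }, error = function(e) FALSE)
  if (!ok)
    stopf("invalid .vsvi descriptor: field 'source_url_pattern' is not a usable (mip, z, row, col) pattern")
  invisible(desc)
}

#' Read a VSVI descriptor file
#'
#' @param path path to a `.vsvi` JSON text file.
#' @return A validated `vsvi_descriptor`.
#' @export
read_vsvi <- function(path) {
  if (!file.exists(path)) stopf("descriptor file not found: %s", path)
  desc <- tryCatch(read_json_file(path), error = function(e)
    stopf("corrupt .vsvi descriptor %s: %s", path, conditionMessage(e)))
  desc$tile_size <- as.integer(desc$tile_size)
  desc$volume_size <- as.integer(desc$volume_size)
  if (!is.null(desc$mip_levels)) desc$mip_levels <- as.integer(desc$mip_levels)
  class(desc) <- "vsvi_descriptor"
  validate_vsvi(desc)
  desc
}

#' Write a volume's VSVI descriptor
#'
#' Emits the JSON-syntax text descriptor for a tile volume so that the
#' prediction (or image) store can be mounted by descriptor-driven viewers.
#' At least one tile must already exist on disk; the descriptor's URL
#' pattern is checked to resolve the volume's first tile.
#'
#' @param vol a `tile_volume`.
#' @param out output file path (conventionally extension `.vsvi`).
#' @param value_semantics optionally override the recorded value semantics.
#' @return The written `vsvi_descriptor`, invisibly.
#' @export
write_vsvi <- function(vol, out = file.path(vol$root, "volume.vsvi"),
                       value_semantics = NULL) {
  stopifnot(inherits(vol, "tile_volume"))
  tiles <- list.files(vol$root, pattern = "\\.png$", recursive = TRUE)
  if (length(tiles) == 0L)
    stopf("cannot write .vsvi for %s: volume has no tiles on disk", vol$root)
  desc <- vol$desc
  if (!is.null(value_semantics)) desc$value_semantics <- value_semantics
  validate_vsvi(desc)
  write_json_file(unclass(desc), out)
  invisible(desc)
}

#' Open (or create) a filesystem tile volume
#'
#' In `"read"` mode, `path` is either a volume directory containing
#' `volume.vsvi` or a path to a `.vsvi` descriptor file. In `"write"` mode
#' a new volume layout is created (the directory tree itself is populated
#' lazily by [write_block()]); `dims` and the storage parameters describe
#' the volume.
#'
#' @param path volume directory or descriptor path.
#' @param mode `"read"` or `"write"`.
#' @param dims (write mode) integer `c(depth, height, width)` extents.
#' @inheritParams vsvi_descriptor
#' @return A `tile_volume` handle exposing extents, mip levels and dtype.
#' @export
open_volume <- function(path, mode = c("read", "write"), dims = NULL,
                        tile_size = 1024L, dtype = "gray8",
                        voxel_size_nm = c(30, 4, 4), mip_levels = 0L,
                        value_semantics = "intensity",
                        source_url_pattern = DEFAULT_NAMING) {
  mode <- match.arg(mode)
  if (mode == "read") {
    if (dir.exists(path)) {
      dfile <- file.path(path, "volume.vsvi")
      root <- path
    } else {
      dfile <- path
      root <- dirname(path)
    }
    if (!file.exists(dfile))
      stopf("no .vsvi descriptor found for volume at %s", path)
    desc <- read_vsvi(dfile)
  } else {
    if (is.null(dims)) stopf("`dims` (depth, height, width) is required in write mode")
    desc <- vsvi_descriptor(volume_size = dims, tile_size = tile_size,
                            dtype = dtype, voxel_size_nm = voxel_size_nm,
                            mip_levels = mip_levels,
                            value_semantics = value_semantics,
                            source_url_pattern = source_url_pattern)
    root <- path
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    write_json_file(unclass(desc), file.path(root, "volume.vsvi"))
  }
  structure(list(root = root, desc = desc), class = "tile_volume")
}

#' @export
print.tile_volume <- function(x, ...) {
  d <- x$desc
  cat(sprintf("<tile_volume> %s\n", x$root))
  cat(sprintf("  extents (z,y,x): %s  tile: %d px  dtype: %s  semantics: %s\n",
              paste(d$volume_size, collapse = " x "), d$tile_size, d$dtype,
              d$value_semantics %||% "?"))
  cat(sprintf("  mip levels: %s\n", paste(d$mip_levels, collapse = ", ")))
  invisible(x)
}

#' Volume extents at a mip level
#'
#' @param vol a `tile_volume`.
#' @param mip downsampling exponent.
#' @return Integer `c(depth, height, width)`; x and y shrink by `2^mip`.
#' @export
volume_dims <- function(vol, mip = 0L) {
  d <- vol$desc$volume_size
  c(d[1L], ceiling(d[2L] / 2^mip), ceiling(d[3L] / 2^mip))
}

tile_path <- function(vol, mip, z, row, col) {
  file.path(vol$root, sprintf(vol$desc$source_url_pattern, mip, z, row, col))
}

empty_tile <- function(vol) {
  ts <- vol$desc$tile_size
  if (vol$desc$dtype == "label24") matrix(0L, ts, ts) else matrix(0, ts, ts)
}

read_tile <- function(vol, mip, z, row, col) {
  p <- tile_path(vol, mip, z, row, col)
  if (!file.exists(p)) return(empty_tile(vol))
  if (vol$desc$dtype == "label24") read_label_png(p) else read_gray_png(p)
}

write_tile <- function(vol, mip, z, row, col, tile) {
  p <- tile_path(vol, mip, z, row, col)
  if (vol$desc$dtype == "label24") write_label_png(tile, p) else write_gray_png(tile, p)
  invisible(p)
}

normalize_roi <- function(roi, dims) {
  if (is.null(roi)) roi <- list(z = c(0L, dims[1L]), y = c(0L, dims[2L]), x = c(0L, dims[3L]))
  for (ax in c("z", "y", "x")) {
    if (is.null(roi[[ax]]) || length(roi[[ax]]) != 2L)
      stopf("roi must have half-open ranges for z, y and x")
    roi[[ax]] <- as.integer(roi[[ax]])
    if (roi[[ax]][1L] < 0L || roi[[ax]][2L] <= roi[[ax]][1L])
      stopf("roi %s range [%d, %d) is empty or negative", ax, roi[[ax]][1L], roi[[ax]][2L])
  }
  lim <- c(z = dims[1L], y = dims[2L], x = dims[3L])
  for (ax in c("z", "y", "x")) {
    if (roi[[ax]][2L] > lim[[ax]])
      stopf("roi %s range [%d, %d) exceeds volume extent %d at this mip",
            ax, roi[[ax]][1L], roi[[ax]][2L], lim[[ax]])
  }
  roi
}

#' Read a region of a tile volume into memory
#'
#' @param vol a `tile_volume`.
#' @param roi half-open 0-based box `list(z = c(z0, z1), y = ..., x = ...)`;
#'   `NULL` reads the whole volume at the chosen mip.
#' @param mip downsampling exponent to read at.
#' @return `[height, width, depth]` array (numeric for `gray8`, integer for
#'   `label24`); voxels never written read back as 0.
#' @export
read_block <- function(vol, roi = NULL, mip = 0L) {
  dims <- volume_dims(vol, mip)
  roi <- normalize_roi(roi, dims)
  ts <- vol$desc$tile_size
  h <- roi$y[2L] - roi$y[1L]; w <- roi$x[2L] - roi$x[1L]; d <- roi$z[2L] - roi$z[1L]
  out <- if (vol$desc$dtype == "label24") array(0L, c(h, w, d)) else array(0, c(h, w, d))
  rows <- seq.int(roi$y[1L] %/% ts, (roi$y[2L] - 1L) %/% ts)
  cols <- seq.int(roi$x[1L] %/% ts, (roi$x[2L] - 1L) %/% ts)
  for (k in seq_len(d)) {
    z <- roi$z[1L] + k - 1L
    for (rr in rows) {
      for (cc in cols) {
        tile <- read_tile(vol, mip, z, rr, cc)
        ty <- rr * ts; tx <- cc * ts
        y0 <- max(roi$y[1L], ty); y1 <- min(roi$y[2L], ty + ts)
        x0 <- max(roi$x[1L], tx); x1 <- min(roi$x[2L], tx + ts)
        out[(y0 - roi$y[1L] + 1L):(y1 - roi$y[1L]),
            (x0 - roi$x[1L] + 1L):(x1 - roi$x[1L]), k] <-
          tile[(y0 - ty + 1L):(y1 - ty), (x0 - tx + 1L):(x1 - tx)]
      }
    }
  }
  out
}

#' Write an image block into a tile volume
#'
#' Each section of the block is split into `tile_size` x `tile_size` PNG
#' tiles which are written (flushed) immediately; partially covered edge
#' tiles are zero-padded to the full tile size so every tile file on disk
#' has identical dimensions.
#'
#' @param vol a `tile_volume` opened in write (or read) mode.
#' @param origin integer `c(z, y, x)` voxel origin, 0-based; the y and x
#'   components must be tile-aligned.
#' @param block `[height, width]` matrix or `[height, width, depth]` array.
#' @param mip mip level to write at.
#' @return The volume handle, invisibly.
#' @export
write_block <- function(vol, origin, block, mip = 0L) {
  stopifnot(inherits(vol, "tile_volume"))
  ts <- vol$desc$tile_size
  origin <- as.integer(origin)
  if (length(origin) != 3L || any(origin < 0L))
    stopf("origin must be non-negative c(z, y, x)")
  if (origin[2L] %% ts != 0L || origin[3L] %% ts != 0L)
    stopf("block origin (y=%d, x=%d) is not aligned to the %d-pixel tile grid",
          origin[2L], origin[3L], ts)
  if (length(dim(block)) == 2L) block <- array(block, c(dim(block), 1L))
  dims <- volume_dims(vol, mip)
  if (origin[1L] + dim(block)[3L] > dims[1L] ||
      origin[2L] + dim(block)[1L] > ceiling(dims[2L] / ts) * ts ||
      origin[3L] + dim(block)[2L] > ceiling(dims[3L] / ts) * ts)
    stopf("block at origin (%s) exceeds the tile-aligned volume extents",
          paste(origin, collapse = ", "))
  h <- dim(block)[1L]; w <- dim(block)[2L]; d <- dim(block)[3L]
  rows <- seq.int(origin[2L] %/% ts, (origin[2L] + h - 1L) %/% ts)
  cols <- seq.int(origin[3L] %/% ts, (origin[3L] + w - 1L) %/% ts)
  for (k in seq_len(d)) {
    z <- origin[1L] + k - 1L
    for (rr in rows) {
      for (cc in cols) {
        ty <- rr * ts; tx <- cc * ts
        y0 <- max(origin[2L], ty); y1 <- min(origin[2L] + h, ty + ts)
        x0 <- max(origin[3L], tx); x1 <- min(origin[3L] + w, tx + ts)
        full <- y1 - y0 == ts && x1 - x0 == ts
        tile <- if (full) empty_tile(vol) else read_tile(vol, mip, z, rr, cc)
        tile[(y0 - ty + 1L):(y1 - ty), (x0 - tx + 1L):(x1 - tx)] <-
          block[(y0 - origin[2L] + 1L):(y1 - origin[2L]),
                (x0 - origin[3L] + 1L):(x1 - origin[3L]), k]
        write_tile(vol, mip, z, rr, cc, tile)
      }
    }
  }
  invisible(vol)
}

#' Chunking parameters for volume traversal
#'
#' Defaults mirror the caching contract of the VAST annotation tool, which
#' holds 16 contiguous sections of 1,024 x 1,024 tiles at a time.
#'
#' @param z_depth sections per chunk (default 16).
#' @param tile chunk footprint side in pixels; a positive multiple of 128.
#' @return A `chunk_spec` object.
#' @export
chunk_spec <- function(z_depth = 16L, tile = 1024L) {
  z_depth <- check_count(z_depth, "z_depth")
  tile <- check_mult128(tile, "tile")
  structure(list(z_depth = z_depth, tile = tile), class = "chunk_spec")
}

#' Plan the chunked traversal of a region
#'
#' Splits the roi into chunks of at most `spec$z_depth` sections by
#' `spec$tile` x `spec$tile` pixels, truncated at the roi edges, ordered
#' z-innermost, then x, then y. The chunks partition the roi exactly.
#'
#' @inheritParams read_block
#' @param spec a [chunk_spec()].
#' @return A data frame with one row per chunk: origin `z0, y0, x0` and
#'   exclusive ends `z1, y1, x1` (voxel coordinates at `mip`).
#' @export
chunk_plan <- function(vol, roi = NULL, mip = 0L, spec = chunk_spec()) {
  dims <- volume_dims(vol, mip)
  roi <- normalize_roi(roi, dims)
  ys <- seq.int(roi$y[1L], roi$y[2L] - 1L, by = spec$tile)
  xs <- seq.int(roi$x[1L], roi$x[2L] - 1L, by = spec$tile)
  zs <- seq.int(roi$z[1L], roi$z[2L] - 1L, by = spec$z_depth)
  grid <- expand.grid(z0 = zs, x0 = xs, y0 = ys,
                      KEEP.OUT.ATTRS = FALSE)  # z varies fastest, then x, then y
  data.frame(
    z0 = grid$z0, y0 = grid$y0, x0 = grid$x0,
    z1 = pmin(grid$z0 + spec$z_depth, roi$z[2L]),
    y1 = pmin(grid$y0 + spec$tile, roi$y[2L]),
    x1 = pmin(grid$x0 + spec$tile, roi$x[2L])
  )
}

#' Read a region chunk by chunk
#'
#' Traverses the roi per [chunk_plan()] (z-innermost order, 16-section
#' default depth) and reads each chunk; together the chunks tile the roi
#' exactly once.
#'
#' @inheritParams chunk_plan
#' @return List of chunks, each `list(origin = c(z, y, x), data = array)`.
#' @export
read_chunks <- function(vol, roi = NULL, mip = 0L, spec = chunk_spec()) {
  plan <- chunk_plan(vol, roi, mip, spec)
  lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    list(origin = c(p$z0, p$y0, p$x0),
         data = read_block(vol, list(z = c(p$z0, p$z1), y = c(p$y0, p$y1),
                                     x = c(p$x0, p$x1)), mip = mip))
  })
}

#' Build mip (downsampling) levels
#'
#' Generates each requested mip level from the level below it: 2x2 block
#' mean for grayscale volumes, stride-2 nearest subsampling for label
#' volumes (averaging label ids would be meaningless). Downsampling acts on
#' x and y only; z is untouched.
#'
#' @param vol a `tile_volume` with mip 0 written.
#' @param levels integer vector of mip levels to build (each >= 1).
#' @return The updated volume handle (descriptor lists the new levels).
#' @export
build_mips <- function(vol, levels = 1L) {
  for (m in sort(as.integer(levels))) {
    src <- m - 1L
    if (!src %in% vol$desc$mip_levels)
      stopf("cannot build mip %d: mip %d is not present", m, src)
    dims <- volume_dims(vol, src)
    for (z in seq.int(0L, dims[1L] - 1L)) {
      sec <- read_block(vol, list(z = c(z, z + 1L), y = c(0L, dims[2L]),
                                  x = c(0L, dims[3L])), mip = src)[, , 1L]
      down <- if (vol$desc$dtype == "label24") {
        sec[seq.int(1L, nrow(sec), 2L), seq.int(1L, ncol(sec), 2L), drop = FALSE]
      } else {
        downsample_mean2(sec)
      }
      write_block(vol, c(z, 0L, 0L), down, mip = m)
    }
    vol$desc$mip_levels <- sort(unique(c(vol$desc$mip_levels, m)))
    write_json_file(unclass(vol$desc), file.path(vol$root, "volume.vsvi"))
  }
  vol
}

# 2x2 block mean with edge replication for odd extents.
downsample_mean2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h %% 2L == 1L) m <- rbind(m, m[h, , drop = FALSE])
  if (w %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  h2 <- nrow(m) / 2L; w2 <- ncol(m) / 2L
  (m[seq.int(1L, nrow(m), 2L), seq.int(1L, ncol(m), 2L), drop = FALSE] +
   m[seq.int(2L, nrow(m), 2L), seq.int(1L, ncol(m), 2L), drop = FALSE] +
   m[seq.int(1L, nrow(m), 2L), seq.int(2L, ncol(m), 2L), drop = FALSE] +
   m[seq.int(2L, nrow(m), 2L), seq.int(2L, ncol(m), 2L), drop = FALSE]) / 4
}
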