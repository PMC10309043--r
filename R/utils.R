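# Shared internal helpers: seeded evaluation, PNG codecs, small validators.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a whole number >= %d", name, min)
  invisible(as.integer(x))
}

check_mult128 <- function(x, name) {
  check_count(x, name)
  if (x %% 128L != 0L)
    stopf("`%s` must be a positive multiple of 128, got %d", name, as.integer(x))
  invisible(as.integer(x))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# --- PNG codecs -------------------------------------------------------------
# Grayscale images are numeric [H, W] matrices on the 0..255 scale.
# Instance/label ids are integer [H, W] matrices; ids are packed into 24-bit
# RGB PNGs (id = R*65536 + G*256 + B), the encoding VAST-style tools use for
# segment exports. Class-index images (small ids + the 255 sentinel) fit in
# 8-bit grayscale PNGs.

write_gray_png <- function(mat, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clamp(round(mat), 0, 255) / 255, path)
  invisible(path)
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * 255)
}

write_label_png <- function(mat, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  id <- as.integer(mat)
  if (any(id < 0L) || any(id > 16777215L)) stopf("label ids must be in [0, 2^24)")
  arr <- array(0, dim = c(nrow(mat), ncol(mat), 3L))
  arr[, , 1L] <- (id %/% 65536L) %% 256L
  arr[, , 2L] <- (id %/% 256L) %% 256L
  arr[, , 3L] <- id %% 256L
  png::writePNG(arr / 255, path)
  invisible(path)
}

read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    out <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    return(out)
  }
  r <- round(img[, , 1L] * 255)
  g <- round(img[, , 2L] * 255)
  b <- round(img[, , 3L] * 255)
  matrix(as.integer(r * 65536 + g * 256 + b), dim(img)[1L], dim(img)[2L])
}

write_class_png <- function(mat, path) {
  if (any(mat < 0L) || any(mat > 255L)) stopf("class indices must fit in 8 bits")
  write_gray_png(mat, path)
}

read_class_png <- function(path) {
  m <- read_gray_png(path)
  matrix(as.integer(m), nrow(m), ncol(m))
}

write_json_file <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Provenance record written next to every CLI/engine artifact.
write_run_log <- function(dir, command, params) {
  write_json_file(list(
    command = command,
    params = params,
    package = "emseg",
    version = as.character(utils::packageVersion("emseg")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), file.path(dir, "run.json"))
}
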