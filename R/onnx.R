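# ONNX interchange for the package's U-net models.
#
# ONNX files are protobuf messages; this module implements the small
# subset of the protobuf wire format and of the ONNX schema (opset 13)
# that the U-net topology needs: Conv, Relu, MaxPool, Resize
# (nearest/asymmetric/floor -- exactly this package's 2x upsampling),
# Concat and Softmax, with float32 weights in NCHW layout. Export
# preserves the architecture and trained weights; import reconstructs a
# `seg_model` that is usable both for inference and for continued
# (transfer) training.

# --- protobuf wire-format primitives ---------------------------------------

pb_varint <- function(x) {
  x <- as.numeric(x)
  if (x < 0) stopf("negative varints are not supported")
  out <- raw(0)
  repeat {
    b <- x %% 128
    x <- (x - b) / 128
    if (x > 0) out <- c(out, as.raw(b + 128)) else return(c(out, as.raw(b)))
  }
}

pb_key <- function(field, wt) pb_varint(field * 8 + wt)

pb_len_field <- function(field, payload) c(pb_key(field, 2), pb_varint(length(payload)), payload)

pb_int_field <- function(field, value) c(pb_key(field, 0), pb_varint(value))

pb_str_field <- function(field, s) pb_len_field(field, charToRaw(enc2utf8(s)))

pb_packed_varints <- function(field, values) {
  pb_len_field(field, do.call(c, lapply(values, pb_varint)))
}

raw_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

# --- ONNX message builders --------------------------------------------------

onnx_tensor <- function(name, dims, values) {
  c(pb_packed_varints(1L, dims),        # dims
    pb_int_field(2L, 1L),               # data_type FLOAT
    pb_str_field(8L, name),             # name
    pb_len_field(9L, raw_f32(values)))  # raw_data (little-endian float32)
}

onnx_attr_int <- function(name, v)
  c(pb_str_field(1L, name), pb_int_field(3L, v), pb_int_field(20L, 2L))
onnx_attr_ints <- function(name, v)
  c(pb_str_field(1L, name), pb_packed_varints(7L, v), pb_int_field(20L, 7L))
onnx_attr_str <- function(name, s)
  c(pb_str_field(1L, name), pb_len_field(4L, charToRaw(s)), pb_int_field(20L, 3L))

onnx_node <- function(op, inputs, outputs, name = op, attrs = list()) {
  parts <- lapply(inputs, function(x) pb_str_field(1L, x))
  parts <- c(parts, lapply(outputs, function(x) pb_str_field(2L, x)))
  parts <- c(parts, list(pb_str_field(3L, name), pb_str_field(4L, op)))
  parts <- c(parts, lapply(attrs, function(a) pb_len_field(5L, a)))
  do.call(c, parts)
}

onnx_value_info <- function(name, dims) {
  dim_msgs <- lapply(dims, function(d) {
    if (is.character(d)) pb_str_field(2L, d) else pb_int_field(1L, d)
  })
  shape <- do.call(c, lapply(dim_msgs, function(m) pb_len_field(1L, m)))
  ttype <- c(pb_int_field(1L, 1L), pb_len_field(2L, shape))  # elem FLOAT + shape
  c(pb_str_field(1L, name), pb_len_field(2L, pb_len_field(1L, ttype)))
}

# Our [k, k, cin, cout] weight layout <-> ONNX's row-major
# (cout, cin, kh, kw): the flat float order needs kw fastest, then kh, ci,
# co, i.e. the column-major order of aperm(w, c(2, 1, 3, 4)).
w_to_onnx <- function(w) as.vector(aperm(w, c(2L, 1L, 3L, 4L)))
w_from_onnx <- function(v, k, cin, cout) aperm(array(v, c(k, k, cin, cout)), c(2L, 1L, 3L, 4L))

#' Export a U-net to an ONNX file
#'
#' Writes the model as an ONNX (opset 13) graph in NCHW layout with
#' float32 weights: Conv/Relu/MaxPool for the contracting path, Resize
#' (nearest, asymmetric, floor) + Conv + Concat for the expanding path and
#' a Softmax head. The file preserves the architecture and trained
#' weights; [import_model()] round-trips it.
#'
#' @param model a `seg_model`.
#' @param path output file path (conventionally `.onnx`).
#' @return `path`, invisibly.
#' @export
export_onnx <- function(model, path) {
  cfg <- model$config
  d <- cfg$depth
  P <- model$params
  nodes <- list()
  inits <- list(onnx_tensor("up_scales", 4L, c(1, 1, 2, 2)))
  cur <- "input"
  emit_conv <- function(nm, input) {
    lay <- P[[nm]]
    k <- dim(lay$w)[1L]
    inits[[length(inits) + 1L]] <<- onnx_tensor(paste0(nm, "_W"), dim(lay$w)[c(4L, 3L, 1L, 2L)],
                                                w_to_onnx(lay$w))
    inits[[length(inits) + 1L]] <<- onnx_tensor(paste0(nm, "_B"), length(lay$b), lay$b)
    attrs <- list(onnx_attr_ints("kernel_shape", c(k, k)),
                  onnx_attr_ints("pads", rep(k %/% 2L, 4L)),
                  onnx_attr_ints("strides", c(1L, 1L)),
                  onnx_attr_int("group", 1L))
    nodes[[length(nodes) + 1L]] <<- onnx_node("Conv", list(input, paste0(nm, "_W"), paste0(nm, "_B")),
                                              list(nm), nm, attrs)
    nm
  }
  emit_relu <- function(input) {
    out <- paste0(input, "_relu")
    nodes[[length(nodes) + 1L]] <<- onnx_node("Relu", list(input), list(out), out)
    out
  }
  skips <- character(d)
  for (i in seq_len(d) - 1L) {
    cur <- emit_relu(emit_conv(sprintf("enc%d_a", i), cur))
    cur <- emit_relu(emit_conv(sprintf("enc%d_b", i), cur))
    skips[i + 1L] <- cur
    out <- sprintf("pool%d", i)
    nodes[[length(nodes) + 1L]] <- onnx_node("MaxPool", list(cur), list(out), out,
                                             list(onnx_attr_ints("kernel_shape", c(2L, 2L)),
                                                  onnx_attr_ints("strides", c(2L, 2L))))
    cur <- out
  }
  cur <- emit_relu(emit_conv(sprintf("enc%d_a", d), cur))
  cur <- emit_relu(emit_conv(sprintf("enc%d_b", d), cur))
  for (i in rev(seq_len(d) - 1L)) {
    out <- sprintf("up%d", i)
    nodes[[length(nodes) + 1L]] <- onnx_node("Resize", list(cur, "", "up_scales"), list(out), out,
                                             list(onnx_attr_str("mode", "nearest"),
                                                  onnx_attr_str("coordinate_transformation_mode", "asymmetric"),
                                                  onnx_attr_str("nearest_mode", "floor")))
    cur <- emit_relu(emit_conv(sprintf("dec%d_up", i), out))
    cat_out <- sprintf("cat%d", i)
    nodes[[length(nodes) + 1L]] <- onnx_node("Concat", list(cur, skips[i + 1L]), list(cat_out),
                                             cat_out, list(onnx_attr_int("axis", 1L)))
    cur <- emit_relu(emit_conv(sprintf("dec%d_a", i), cat_out))
    cur <- emit_relu(emit_conv(sprintf("dec%d_b", i), cur))
  }
  cur <- emit_conv("head", cur)
  nodes[[length(nodes) + 1L]] <- onnx_node("Softmax", list(cur), list("prob"), "softmax",
                                           list(onnx_attr_int("axis", 1L)))
  graph <- do.call(c, c(
    lapply(nodes, function(n) pb_len_field(1L, n)),
    list(pb_str_field(2L, "unet")),
    lapply(inits, function(t) pb_len_field(5L, t)),
    list(pb_len_field(11L, onnx_value_info("input", list(1L, cfg$in_channels, "H", "W"))),
         pb_len_field(12L, onnx_value_info("prob", list(1L, cfg$n_classes, "H", "W"))))))
  opset <- pb_int_field(2L, 13L)
  msg <- c(pb_int_field(1L, 8L),                 # ir_version
           pb_str_field(2L, "emseg"),            # producer_name
           pb_str_field(3L, as.character(utils::packageVersion("emseg"))),
           pb_len_field(7L, graph),
           pb_len_field(8L, opset))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeBin(msg, path)
  invisible(path)
}

# --- protobuf reader --------------------------------------------------------

pb_read_varint <- function(buf, pos) {
  val <- 0; shift <- 1
  repeat {
    if (pos > length(buf)) stopf("truncated or corrupt ONNX file (unexpected end of varint)")
    b <- as.integer(buf[pos]); pos <- pos + 1
    val <- val + (b %% 128) * shift
    if (b < 128) return(list(val = val, pos = pos))
    shift <- shift * 128
  }
}

# Parse one protobuf message into a list of fields (field number, wire
# type, value: numeric for varints, raw payload for length-delimited).
pb_parse <- function(buf) {
  pos <- 1
  fields <- list()
  while (pos <= length(buf)) {
    k <- pb_read_varint(buf, pos); pos <- k$pos
    field <- k$val %/% 8
    wt <- k$val %% 8
    if (wt == 0) {
      v <- pb_read_varint(buf, pos); pos <- v$pos
      value <- v$val
    } else if (wt == 2) {
      l <- pb_read_varint(buf, pos); pos <- l$pos
      if (pos + l$val - 1 > length(buf))
        stopf("truncated or corrupt ONNX file (field %d payload overruns buffer)", field)
      value <- if (l$val > 0) buf[pos:(pos + l$val - 1)] else raw(0)
      pos <- pos + l$val
    } else if (wt == 5) {
      if (pos + 3 > length(buf)) stopf("truncated or corrupt ONNX file")
      value <- readBin(buf[pos:(pos + 3)], "numeric", size = 4, endian = "little")
      pos <- pos + 4
    } else if (wt == 1) {
      if (pos + 7 > length(buf)) stopf("truncated or corrupt ONNX file")
      value <- readBin(buf[pos:(pos + 7)], "double", endian = "little")
      pos <- pos + 8
    } else {
      stopf("unsupported protobuf wire type %d in ONNX file", wt)
    }
    fields[[length(fields) + 1L]] <- list(field = field, wt = wt, value = value)
  }
  fields
}

pb_field_all <- function(fields, no) Filter(function(f) f$field == no, fields)
pb_field_one <- function(fields, no) {
  hits <- pb_field_all(fields, no)
  if (length(hits) == 0) NULL else hits[[1L]]$value
}

pb_unpack_varints <- function(payload) {
  pos <- 1; out <- numeric(0)
  while (pos <= length(payload)) {
    v <- pb_read_varint(payload, pos); pos <- v$pos
    out <- c(out, v$val)
  }
  out
}

parse_onnx_tensor <- function(buf) {
  f <- pb_parse(buf)
  dims <- numeric(0)
  for (df in pb_field_all(f, 1)) {
    dims <- c(dims, if (df$wt == 2) pb_unpack_varints(df$value) else df$value)
  }
  dtype <- pb_field_one(f, 2) %||% 1
  if (dtype != 1) stopf("unsupported ONNX tensor data type %d (only float32)", dtype)
  name <- rawToChar(pb_field_one(f, 8) %||% raw(0))
  rawd <- pb_field_one(f, 9)
  vals <- if (!is.null(rawd)) {
    readBin(rawd, "numeric", n = length(rawd) / 4, size = 4, endian = "little")
  } else {
    fd <- pb_field_all(f, 4)   # packed float_data
    if (length(fd) == 1 && fd[[1L]]$wt == 2)
      readBin(fd[[1L]]$value, "numeric", n = length(fd[[1L]]$value) / 4,
              size = 4, endian = "little")
    else vapply(fd, function(x) x$value, numeric(1))
  }
  list(name = name, dims = dims, values = vals)
}

parse_onnx_node <- function(buf) {
  f <- pb_parse(buf)
  attrs <- list()
  for (af in pb_field_all(f, 5)) {
    a <- pb_parse(af$value)
    nm <- rawToChar(pb_field_one(a, 1) %||% raw(0))
    attrs[[nm]] <- list(i = pb_field_one(a, 3),
                        ints = { p <- pb_field_all(a, 7)
                                 if (length(p) > 0 && p[[1L]]$wt == 2)
                                   pb_unpack_varints(p[[1L]]$value)
                                 else vapply(p, function(x) x$value, numeric(1)) },
                        s = { s <- pb_field_one(a, 4); if (is.null(s)) NULL else rawToChar(s) })
  }
  list(op = rawToChar(pb_field_one(f, 4) %||% raw(0)),
       name = rawToChar(pb_field_one(f, 3) %||% raw(0)),
       inputs = vapply(pb_field_all(f, 1), function(x) rawToChar(x$value), character(1)),
       outputs = vapply(pb_field_all(f, 2), function(x) rawToChar(x$value), character(1)),
       attrs = attrs)
}

#' Import a U-net from an ONNX file
#'
#' Parses the ONNX protobuf and reconstructs a `seg_model` when the graph
#' matches the 2D U-net topology this package evaluates tile-wise
#' (Conv/Relu/MaxPool contracting path, Resize + Conv + Concat expanding
#' path, Softmax head, NCHW float32). Depth, base channels, input channels
#' and class count are inferred from the graph. Graphs containing other
#' operators, or shapes incompatible with tiled 2D inference, are rejected
#' with a descriptive error; truncated files raise a parse error.
#'
#' @param path path to an `.onnx` file.
#' @return A `seg_model` usable for inference and continued training.
#' @export
import_model <- function(path) {
  if (!file.exists(path)) stopf("ONNX file not found: %s", path)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) == 0) stopf("truncated or corrupt ONNX file (empty)")
  top <- pb_parse(buf)
  graph_raw <- pb_field_one(top, 7)
  if (is.null(graph_raw)) stopf("not an ONNX model: no graph found")
  g <- pb_parse(graph_raw)
  nodes <- lapply(pb_field_all(g, 1), function(x) parse_onnx_node(x$value))
  inits <- lapply(pb_field_all(g, 5), function(x) parse_onnx_tensor(x$value))
  names(inits) <- vapply(inits, function(t) t$name, character(1))
  ops <- vapply(nodes, function(n) n$op, character(1))
  supported <- c("Conv", "Relu", "MaxPool", "Resize", "Upsample", "Concat", "Softmax")
  bad <- setdiff(unique(ops), supported)
  if (length(bad) > 0)
    stopf("unsupported ONNX operator(s): %s", paste(bad, collapse = ", "))
  convs <- nodes[ops == "Conv"]
  if (length(convs) == 0) stopf("ONNX graph has no Conv layers")
  get_w <- function(node) {
    wn <- node$inputs[2L]
    if (!wn %in% names(inits)) stopf("Conv weight initializer %s missing", wn)
    inits[[wn]]
  }
  wd1 <- get_w(convs[[1L]])$dims
  if (length(wd1) != 4) stopf("Conv weights must be rank 4 (2D convolution) for tiled inference")
  depth <- sum(ops == "MaxPool")
  cfg <- unet_config(depth = depth,
                     base_channels = as.integer(wd1[1L]),
                     n_classes = as.integer(get_w(convs[[length(convs)]])$dims[1L]),
                     in_channels = as.integer(wd1[2L]))
  plan <- unet_layer_plan(cfg)
  if (length(convs) != length(plan))
    stopf("ONNX graph has %d Conv layers; the inferred depth-%d U-net needs %d",
          length(convs), depth, length(plan))
  model <- build_unet(cfg, seed = 0L)
  for (t in seq_along(plan)) {
    lay <- plan[[t]]
    wt <- get_w(convs[[t]])
    if (!all(wt$dims == c(lay$cout, lay$cin, lay$k, lay$k)))
      stopf("Conv %s has shape (%s); expected (%d, %d, %d, %d) for layer %s",
            convs[[t]]$name, paste(wt$dims, collapse = ", "),
            lay$cout, lay$cin, lay$k, lay$k, lay$name)
    bn <- convs[[t]]$inputs[3L]
    bias <- if (!is.na(bn) && bn %in% names(inits)) inits[[bn]]$values else numeric(lay$cout)
    model$params[[lay$name]]$w <- w_from_onnx(wt$values, lay$k, lay$cin, lay$cout)
    model$params[[lay$name]]$b <- bias
  }
  model
}
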