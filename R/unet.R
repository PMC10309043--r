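# 2D U-net semantic segmentation: model construction, forward and backward
# passes. The network is the standard encoder-decoder with skip
# connections (contracting path: two 3x3 conv + ReLU per level, 2x2 max
# pool; expanding path: nearest-neighbour 2x upsampling, 3x3 conv, skip
# concatenation, two 3x3 conv + ReLU; 1x1 conv head with per-pixel
# softmax). Parameters are grouped encoder / decoder / head so that the
# transfer-learning schedules (freezing, leaky freeze) can address them.

#' U-net architecture configuration
#'
#' @param depth number of pooling steps (the contracting path has
#'   `depth + 1` levels including the bottleneck). Input sides must be
#'   divisible by `2^depth`; the package's 128-multiple patch contract
#'   guarantees this for `depth <= 7`.
#' @param base_channels feature channels at the first level; level `i`
#'   uses `base_channels * 2^i`.
#' @param n_classes 2 or 3 output classes.
#' @param in_channels input image channels (1 for grayscale EM).
#' @return A `unet_config` object.
#' @export
unet_config <- function(depth = 3L, base_channels = 16L, n_classes = 2L,
                        in_channels = 1L) {
  depth <- check_count(depth, "depth")
  if (depth > 7L) stopf("depth must be <= 7")
  base_channels <- check_count(base_channels, "base_channels")
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 in_channels = check_count(in_channels, "in_channels")),
            class = "unet_config")
}

unet_channels <- function(cfg, i) cfg$base_channels * 2L^i

# Ordered parameter-layer plan: name, kernel, in/out channels, group.
unet_layer_plan <- function(cfg) {
  d <- cfg$depth
  plan <- list()
  cin <- cfg$in_channels
  for (i in 0:d) {
    c_i <- unet_channels(cfg, i)
    plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d_a", i), k = 3L,
                                      cin = cin, cout = c_i, group = "encoder")
    plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d_b", i), k = 3L,
                                      cin = c_i, cout = c_i, group = "encoder")
    cin <- c_i
  }
  for (i in (d - 1):0) {
    c_i <- unet_channels(cfg, i)
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_up", i), k = 3L,
                                      cin = unet_channels(cfg, i + 1L),
                                      cout = c_i, group = "decoder")
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_a", i), k = 3L,
                                      cin = 2L * c_i, cout = c_i, group = "decoder")
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_b", i), k = 3L,
                                      cin = c_i, cout = c_i, group = "decoder")
  }
  plan[[length(plan) + 1L]] <- list(name = "head", k = 1L,
                                    cin = unet_channels(cfg, 0L),
                                    cout = cfg$n_classes, group = "head")
  plan
}

#' Build a randomly initialized U-net
#'
#' He (fan-in) initialization, deterministic under the seed.
#'
#' @param cfg a [unet_config()].
#' @param seed RNG seed for the initialization.
#' @return A `seg_model`: configuration plus named parameter tensors with
#'   encoder/decoder/head group tags.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  plan <- unet_layer_plan(cfg)
  params <- with_seed(seed, {
    out <- list()
    for (lay in plan) {
      n <- lay$k * lay$k * lay$cin * lay$cout
      sd <- sqrt(2 / (lay$k * lay$k * lay$cin))
      out[[lay$name]] <- list(
        w = array(rnorm(n, sd = sd), dim = c(lay$k, lay$k, lay$cin, lay$cout)),
        b = numeric(lay$cout),
        group = lay$group)
    }
    out
  })
  structure(list(config = cfg, params = params, history = NULL),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), numeric(1)))
  cat(sprintf("<seg_model> U-net depth %d, base %d channels, %d classes, %s parameters\n",
              cfg$depth, cfg$base_channels, cfg$n_classes, format(np, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (final val loss %.4f)\n",
                max(x$history$epoch), tail(x$history$val_loss, 1L)))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

upsample2 <- function(a) {
  d <- dim(a)
  a[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  odd_r <- seq.int(1L, d[1L], 2L); odd_c <- seq.int(1L, d[2L], 2L)
  dy[odd_r, odd_c, , drop = FALSE] + dy[odd_r + 1L, odd_c, , drop = FALSE] +
    dy[odd_r, odd_c + 1L, , drop = FALSE] + dy[odd_r + 1L, odd_c + 1L, , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1L], da[2L], da[3L] + db[3L]))
}

softmax3 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[3L])
  mx <- m[, 1L]
  for (k in seq_len(d[3L])[-1L]) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  array(e / rowSums(e), dim = d)
}

# Scale a 0..255 grayscale section to the network's centred input range.
prep_input <- function(em) {
  array(em / 255 - 0.5, dim = c(nrow(em), ncol(em), 1L))
}

# Forward pass. keep = TRUE retains every intermediate needed by
# backward_unet in `cache`.
forward_unet <- function(model, x, keep = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  if (dim(x)[1L] %% 2L^d != 0L || dim(x)[2L] %% 2L^d != 0L)
    stopf("input sides must be divisible by 2^depth = %d", 2L^d)
  P <- model$params
  cache <- if (keep) new.env(parent = emptyenv()) else NULL
  conv_layer <- function(a, name) {
    if (keep) assign(paste0(name, "_x"), a, envir = cache)
    cpp_conv2d_fwd(a, P[[name]]$w, P[[name]]$b)
  }
  relu_layer <- function(z, name) {
    a <- relu(z)
    if (keep) assign(paste0(name, "_m"), z > 0, envir = cache)
    a
  }
  skips <- vector("list", d)
  a <- x
  for (i in seq_len(d) - 1L) {
    a <- relu_layer(conv_layer(a, sprintf("enc%d_a", i)), sprintf("enc%d_a", i))
    a <- relu_layer(conv_layer(a, sprintf("enc%d_b", i)), sprintf("enc%d_b", i))
    skips[[i + 1L]] <- a
    pooled <- cpp_maxpool2_fwd(a)
    if (keep) assign(sprintf("pool%d", i),
                     list(idx = pooled$idx, h = dim(a)[1L], w = dim(a)[2L]),
                     envir = cache)
    a <- pooled$y
  }
  a <- relu_layer(conv_layer(a, sprintf("enc%d_a", d)), sprintf("enc%d_a", d))
  a <- relu_layer(conv_layer(a, sprintf("enc%d_b", d)), sprintf("enc%d_b", d))
  for (i in rev(seq_len(d) - 1L)) {
    u <- upsample2(a)
    r <- relu_layer(conv_layer(u, sprintf("dec%d_up", i)), sprintf("dec%d_up", i))
    a <- concat_c(r, skips[[i + 1L]])
    if (keep) assign(sprintf("split%d", i), dim(r)[3L], envir = cache)
    a <- relu_layer(conv_layer(a, sprintf("dec%d_a", i)), sprintf("dec%d_a", i))
    a <- relu_layer(conv_layer(a, sprintf("dec%d_b", i)), sprintf("dec%d_b", i))
  }
  logits <- conv_layer(a, "head")
  list(prob = softmax3(logits), logits = logits, cache = cache)
}

# Backward pass through the whole net given d(loss)/d(logits).
backward_unet <- function(model, cache, dlogits) {
  cfg <- model$config
  d <- cfg$depth
  P <- model$params
  grads <- list()
  conv_bwd <- function(dy, name) {
    g <- cpp_conv2d_bwd(get(paste0(name, "_x"), envir = cache), P[[name]]$w, dy)
    grads[[name]] <<- list(w = g$dw, b = g$db)
    g$dx
  }
  relu_bwd <- function(da, name) da * get(paste0(name, "_m"), envir = cache)
  da <- conv_bwd(dlogits, "head")
  dskip <- vector("list", d)
  for (i in seq_len(d) - 1L) {
    da <- conv_bwd(relu_bwd(da, sprintf("dec%d_b", i)), sprintf("dec%d_b", i))
    da <- conv_bwd(relu_bwd(da, sprintf("dec%d_a", i)), sprintf("dec%d_a", i))
    nup <- get(sprintf("split%d", i), envir = cache)
    dr <- da[, , seq_len(nup), drop = FALSE]
    dskip[[i + 1L]] <- da[, , -seq_len(nup), drop = FALSE]
    du <- conv_bwd(relu_bwd(dr, sprintf("dec%d_up", i)), sprintf("dec%d_up", i))
    da <- upsample2_bwd(du)
  }
  da <- conv_bwd(relu_bwd(da, sprintf("enc%d_b", d)), sprintf("enc%d_b", d))
  da <- conv_bwd(relu_bwd(da, sprintf("enc%d_a", d)), sprintf("enc%d_a", d))
  for (i in rev(seq_len(d) - 1L)) {
    pool <- get(sprintf("pool%d", i), envir = cache)
    da <- cpp_maxpool2_bwd(pool$idx, da, pool$h, pool$w)
    da <- da + dskip[[i + 1L]]
    da <- conv_bwd(relu_bwd(da, sprintf("enc%d_b", i)), sprintf("enc%d_b", i))
    da <- conv_bwd(relu_bwd(da, sprintf("enc%d_a", i)), sprintf("enc%d_a", i))
  }
  grads
}

# Weighted per-pixel cross-entropy; unlabeled sentinel pixels are excluded.
# Returns the loss and d(loss)/d(logits).
ce_loss <- function(prob, target, class_weights = NULL,
                    unlabeled = EMSEG_UNLABELED) {
  d <- dim(prob)
  K <- d[3L]
  tv <- as.vector(target)
  valid <- tv != unlabeled
  if (!any(valid)) stopf("no labeled pixels in batch")
  w <- rep(0, length(tv))
  w[valid] <- if (is.null(class_weights)) 1 else class_weights[tv[valid] + 1L]
  pm <- matrix(prob, ncol = K)
  pt <- pm[cbind(seq_along(tv)[valid], tv[valid] + 1L)]
  wsum <- sum(w)
  loss <- -sum(w[valid] * log(pmax(pt, 1e-12))) / wsum
  onehot <- matrix(0, length(tv), K)
  onehot[cbind(seq_along(tv)[valid], tv[valid] + 1L)] <- 1
  dlogits <- array((pm - onehot) * (w / wsum), dim = d)
  list(loss = loss, dlogits = dlogits)
}

#' Average loss gradients over a batch of patches
#'
#' Runs forward and backward passes for every EM/label pair and averages
#' the parameter gradients -- the quantity one optimizer step consumes.
#' Exposed so that update rules (e.g. the leaky-freeze scaling contract)
#' can be verified against the closed-form SGD step.
#'
#' @param model a `seg_model`.
#' @param ems list of grayscale patches (0..255).
#' @param labels list of class-index patches.
#' @param class_weights optional per-class loss weights.
#' @return `list(grads = named list of w/b gradients, loss = mean batch loss)`.
#' @export
unet_gradients <- function(model, ems, labels, class_weights = NULL) {
  acc <- NULL
  loss <- 0
  n <- length(ems)
  for (i in seq_len(n)) {
    fw <- forward_unet(model, prep_input(ems[[i]]), keep = TRUE)
    l <- ce_loss(fw$prob, labels[[i]], class_weights)
    g <- backward_unet(model, fw$cache, l$dlogits)
    loss <- loss + l$loss / n
    if (is.null(acc)) {
      acc <- g
    } else {
      for (nm in names(acc)) {
        acc[[nm]]$w <- acc[[nm]]$w + g[[nm]]$w
        acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
      }
    }
  }
  for (nm in names(acc)) {
    acc[[nm]]$w <- acc[[nm]]$w / n
    acc[[nm]]$b <- acc[[nm]]$b / n
  }
  list(grads = acc, loss = loss)
}

#' Predict class probabilities for a grayscale section
#'
#' @param model a `seg_model`.
#' @param em grayscale matrix (0..255) whose sides are divisible by
#'   `2^depth`; apply the dataset's stored grayscale correction first (or
#'   pass `preprocess`).
#' @param preprocess optional fitted [preprocess_params()] applied before
#'   prediction.
#' @return `[H, W, n_classes]` probability array; class probabilities sum
#'   to 1 at every pixel.
#' @export
predict_unet <- function(model, em, preprocess = NULL) {
  if (!is.null(preprocess)) em <- stretch_grayscale(em, preprocess)
  forward_unet(model, prep_input(em))$prob
}
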