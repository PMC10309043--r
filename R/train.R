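# Training loop and transfer-learning schedules.
#
# Modes:
#   scratch / continuous -- every parameter trains (continuous learning is
#     retraining a pretrained model unchanged on new data);
#   freeze_last          -- only the 1x1 classification head trains;
#   freeze_encoder       -- the contracting path is fixed;
#   leaky_freeze         -- the encoder trains at `leaky_factor` times the
#     decoder's learning rate (default 0.1);
#   episodic             -- batches interleave between two (or more)
#     datasets at a fixed ratio, guarding against catastrophic forgetting.

#' Training configuration
#'
#' @param epochs passes over the training split.
#' @param batch_size patches per optimizer step.
#' @param lr learning rate (the decoder/head rate under `leaky_freeze`).
#' @param momentum SGD momentum coefficient.
#' @param optimizer `"sgd"` (momentum SGD, the default so that one update
#'   step has a closed form) or `"adam"`.
#' @param mode one of `"scratch"`, `"continuous"`, `"freeze_last"`,
#'   `"freeze_encoder"`, `"leaky_freeze"`, `"episodic"`.
#' @param leaky_factor encoder learning-rate multiplier for
#'   `leaky_freeze`; must lie in (0, 1].
#' @param episodic_ratio batches drawn from the first dataset per batch
#'   drawn from each other dataset in `episodic` mode.
#' @param class_weights `NULL`, `"inverse"` (inverse pixel frequency,
#'   normalized to mean 1) or a numeric vector of per-class loss weights.
#' @param seed RNG seed: fixed seed + fixed data give identical learning
#'   curves.
#' @param checkpoint_dir if set, an ONNX snapshot is written there at
#'   every epoch end.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 10L, batch_size = 4L, lr = 0.01,
                         momentum = 0.9, optimizer = c("sgd", "adam"),
                         mode = c("scratch", "continuous", "freeze_last",
                                  "freeze_encoder", "leaky_freeze", "episodic"),
                         leaky_factor = 0.1, episodic_ratio = 1L,
                         class_weights = NULL, seed = 1L,
                         checkpoint_dir = NULL) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer)
  if (leaky_factor <= 0 || leaky_factor > 1) stopf("leaky_factor must be in (0, 1]")
  if (episodic_ratio < 1) stopf("episodic_ratio must be >= 1")
  structure(list(epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 lr = lr, momentum = momentum, optimizer = optimizer,
                 mode = mode, leaky_factor = leaky_factor,
                 episodic_ratio = as.integer(episodic_ratio),
                 class_weights = class_weights, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

group_multipliers <- function(cfg) {
  switch(cfg$mode,
    scratch = ,
    continuous = ,
    episodic = c(encoder = 1, decoder = 1, head = 1),
    freeze_last = c(encoder = 0, decoder = 0, head = 1),
    freeze_encoder = c(encoder = 0, decoder = 1, head = 1),
    leaky_freeze = c(encoder = cfg$leaky_factor, decoder = 1, head = 1))
}

resolve_class_weights <- function(cfg, datasets) {
  if (is.null(cfg$class_weights)) return(NULL)
  if (is.numeric(cfg$class_weights)) return(cfg$class_weights)
  if (identical(cfg$class_weights, "inverse")) {
    freq <- Reduce(`+`, lapply(datasets, class_frequencies)) / length(datasets)
    w <- 1 / pmax(freq, 1e-6)
    return(w / mean(w))
  }
  stopf("class_weights must be NULL, \"inverse\" or a numeric vector")
}

split_indices <- function(ds, split) which(ds$manifest$split == split)

# Evaluate mean loss / accuracy / balanced accuracy over given patches.
evaluate_patches <- function(model, ds, idx, class_weights) {
  if (length(idx) == 0L) return(c(loss = NA_real_, acc = NA_real_, bacc = NA_real_))
  loss <- 0; correct <- 0; total <- 0
  K <- model$config$n_classes
  hits <- numeric(K); counts <- numeric(K)
  for (i in idx) {
    prob <- forward_unet(model, prep_input(ds$em[[i]]))$prob
    l <- ce_loss(prob, ds$labels[[i]], class_weights)
    loss <- loss + l$loss / length(idx)
    pred <- categorical_from_prob(prob)
    truth <- ds$labels[[i]]
    valid <- truth != EMSEG_UNLABELED
    correct <- correct + sum(pred[valid] == truth[valid])
    total <- total + sum(valid)
    for (k in seq_len(K) - 1L) {
      sel <- valid & truth == k
      counts[k + 1L] <- counts[k + 1L] + sum(sel)
      hits[k + 1L] <- hits[k + 1L] + sum(pred[sel] == k)
    }
  }
  present <- counts > 0
  c(loss = loss, acc = correct / total,
    bacc = mean((hits / pmax(counts, 1))[present]))
}

#' Train a U-net on one or more patch datasets
#'
#' Momentum-SGD (or Adam) minimization of per-pixel cross-entropy under
#' the configured transfer-learning schedule. Per-epoch training loss and
#' validation loss/accuracy are recorded as learning curves; epoch 0 holds
#' the pre-training metrics. Training is deterministic given the seed.
#'
#' @param model a `seg_model` (freshly built or imported).
#' @param data a `patch_dataset`, or a list of them for `episodic` mode
#'   (the first is the primary dataset).
#' @param cfg a [train_config()].
#' @return `list(model = trained seg_model, history = data.frame)` with
#'   per-epoch `train_loss`, `val_loss`, `val_acc`, `val_bacc`.
#' @export
train_unet <- function(model, data, cfg = train_config()) {
  datasets <- if (inherits(data, "patch_dataset")) list(data) else data
  if (length(datasets) == 0L || length(datasets[[1L]]$em) == 0L)
    stopf("empty training dataset")
  for (ds in datasets) {
    if (!inherits(ds, "patch_dataset")) stopf("data must be patch_dataset(s)")
    if (ds$config$n_classes != model$config$n_classes)
      stopf("dataset has %d classes but the model predicts %d",
            ds$config$n_classes, model$config$n_classes)
  }
  if (cfg$mode == "episodic" && length(datasets) < 2L)
    stopf("episodic mode needs at least two datasets")
  cw <- resolve_class_weights(cfg, datasets)
  mult <- group_multipliers(cfg)
  state <- new.env(parent = emptyenv())
  history <- list()
  primary <- datasets[[1L]]
  val_idx <- split_indices(primary, "val")
  ev0 <- evaluate_patches(model, primary, val_idx, cw)
  tr0 <- evaluate_patches(model, primary, split_indices(primary, "train"), cw)
  history[[1L]] <- data.frame(epoch = 0L, train_loss = tr0[["loss"]],
                              val_loss = ev0[["loss"]], val_acc = ev0[["acc"]],
                              val_bacc = ev0[["bacc"]])
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      batches <- make_batches(datasets, cfg)
      ep_loss <- 0
      for (b in batches) {
        ds <- datasets[[b$dataset]]
        g <- unet_gradients(model, ds$em[b$idx], ds$labels[b$idx], cw)
        ep_loss <- ep_loss + g$loss / length(batches)
        model <- apply_update(model, g$grads, cfg, mult, state)
      }
      ev <- evaluate_patches(model, primary, val_idx, cw)
      history[[epoch + 1L]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                          val_loss = ev[["loss"]],
                                          val_acc = ev[["acc"]],
                                          val_bacc = ev[["bacc"]])
      if (!is.null(cfg$checkpoint_dir)) {
        dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        export_onnx(model, file.path(cfg$checkpoint_dir,
                                     sprintf("epoch_%03d.onnx", epoch)))
      }
    }
  })
  model$history <- do.call(rbind, history)
  list(model = model, history = model$history)
}

# Shuffled batch schedule for one epoch. Episodic mode interleaves:
# `episodic_ratio` batches from dataset 1, then one from each other
# dataset, repeating.
make_batches <- function(datasets, cfg) {
  per_ds <- lapply(datasets, function(ds) {
    idx <- sample(split_indices(ds, "train"))
    split(idx, ceiling(seq_along(idx) / cfg$batch_size))
  })
  if (cfg$mode != "episodic") {
    return(lapply(per_ds[[1L]], function(ix) list(dataset = 1L, idx = ix)))
  }
  out <- list()
  cursors <- rep(1L, length(datasets))
  n1 <- length(per_ds[[1L]])
  while (cursors[1L] <= n1) {
    for (r in seq_len(cfg$episodic_ratio)) {
      if (cursors[1L] > n1) break
      out[[length(out) + 1L]] <- list(dataset = 1L, idx = per_ds[[1L]][[cursors[1L]]])
      cursors[1L] <- cursors[1L] + 1L
    }
    for (dsi in seq_along(datasets)[-1L]) {
      k <- length(per_ds[[dsi]])
      take <- ((cursors[dsi] - 1L) %% k) + 1L
      out[[length(out) + 1L]] <- list(dataset = dsi, idx = per_ds[[dsi]][[take]])
      cursors[dsi] <- cursors[dsi] + 1L
    }
  }
  out
}

apply_update <- function(model, grads, cfg, mult, state) {
  for (nm in names(grads)) {
    group <- model$params[[nm]]$group
    lr_eff <- cfg$lr * mult[[group]]
    if (lr_eff == 0) next
    for (slot in c("w", "b")) {
      g <- grads[[nm]][[slot]]
      key <- paste0(nm, "_", slot)
      if (cfg$optimizer == "sgd") {
        v <- if (exists(key, envir = state)) get(key, envir = state) else 0
        v <- cfg$momentum * v - lr_eff * g
        assign(key, v, envir = state)
        model$params[[nm]][[slot]] <- model$params[[nm]][[slot]] + v
      } else {
        st <- if (exists(key, envir = state)) get(key, envir = state)
              else list(m = 0, v = 0, t = 0)
        st$t <- st$t + 1
        st$m <- 0.9 * st$m + 0.1 * g
        st$v <- 0.999 * st$v + 0.001 * g^2
        mhat <- st$m / (1 - 0.9^st$t)
        vhat <- st$v / (1 - 0.999^st$t)
        assign(key, st, envir = state)
        model$params[[nm]][[slot]] <-
          model$params[[nm]][[slot]] - lr_eff * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  }
  model
}

#' Segmentation quality metrics
#'
#' @param pred,truth integer class-index matrices; unlabeled sentinel
#'   pixels in `truth` are ignored.
#' @param n_classes number of classes.
#' @return List with overall `accuracy`, `balanced_accuracy` (mean
#'   per-class recall) and per-class `precision`, `recall`, `f1`.
#' @export
seg_metrics <- function(pred, truth, n_classes) {
  valid <- truth != EMSEG_UNLABELED
  p <- pred[valid]; t <- truth[valid]
  precision <- recall <- f1 <- numeric(n_classes)
  for (k in seq_len(n_classes) - 1L) {
    tp <- sum(p == k & t == k)
    precision[k + 1L] <- if (sum(p == k) > 0) tp / sum(p == k) else NA_real_
    recall[k + 1L] <- if (sum(t == k) > 0) tp / sum(t == k) else NA_real_
    f1[k + 1L] <- if (!is.na(precision[k + 1L]) && !is.na(recall[k + 1L]) &&
                      precision[k + 1L] + recall[k + 1L] > 0)
      2 * precision[k + 1L] * recall[k + 1L] / (precision[k + 1L] + recall[k + 1L])
    else NA_real_
  }
  list(accuracy = mean(p == t),
       balanced_accuracy = mean(recall, na.rm = TRUE),
       precision = precision, recall = recall, f1 = f1)
}
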