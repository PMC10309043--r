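test_that("the U-net honours its shape and normalization contracts", {
  model <- build_unet(unet_config(depth = 3L, base_channels = 4L, n_classes = 3L),
                      seed = 2L)
  em <- matrix(runif(128 * 128) * 255, 128, 128)
  prob <- predict_unet(model, em)
  expect_equal(dim(prob), c(128L, 128L, 3L))
  sums <- apply(prob, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  # identical seeds give identical initial parameters
  m2 <- build_unet(unet_config(depth = 3L, base_channels = 4L, n_classes = 3L),
                   seed = 2L)
  expect_identical(flatten_params(model), flatten_params(m2))
  m3 <- build_unet(unet_config(depth = 3L, base_channels = 4L, n_classes = 3L),
                   seed = 3L)
  expect_false(identical(flatten_params(model), flatten_params(m3)))
  # input not divisible by 2^depth
  expect_error(predict_unet(model, matrix(0, 100, 100)), "divisible")
  expect_error(unet_config(n_classes = 4L), "2 or 3")
})

test_that("freeze modes train exactly the stated parameter groups", {
  ds <- mosaic_dataset(n_patches = 4L, seed = 3L, val_fraction = 0)
  model <- tiny_unet(depth = 1L, base = 2L, seed = 5L)
  groups <- vapply(model$params, `[[`, character(1), "group")
  for (mode in c("freeze_encoder", "freeze_last")) {
    fit <- train_unet(model, ds, train_config(epochs = 1L, batch_size = 4L,
                                              mode = mode, seed = 1L))
    frozen <- switch(mode, freeze_encoder = "encoder",
                     freeze_last = c("encoder", "decoder"))
    for (nm in names(model$params)) {
      same <- identical(fit$model$params[[nm]]$w, model$params[[nm]]$w)
      expect_equal(same, groups[[nm]] %in% frozen, label = paste(mode, nm))
    }
  }
})

test_that("one leaky-freeze SGD step scales the encoder update by the factor", {
  ds <- mosaic_dataset(n_patches = 4L, seed = 4L, val_fraction = 0)
  model <- tiny_unet(depth = 1L, base = 2L, seed = 9L)
  idx <- which(ds$manifest$split == "train")
  g <- unet_gradients(model, ds$em[idx], ds$labels[idx])
  lr <- 0.01; factor <- 0.1
  fit <- train_unet(model, ds,
                    train_config(epochs = 1L, batch_size = length(idx), lr = lr,
                                 mode = "leaky_freeze", leaky_factor = factor,
                                 seed = 1L))
  for (nm in names(model$params)) {
    delta <- fit$model$params[[nm]]$w - model$params[[nm]]$w
    mult <- if (model$params[[nm]]$group == "encoder") factor else 1
    # closed form of the first momentum-SGD step: delta = -lr * mult * grad
    expect_equal(delta, -lr * mult * g$grads[[nm]]$w, tolerance = 1e-8)
  }
})

test_that("training reduces the validation loss below its epoch-0 value", {
  ds <- mosaic_dataset(n_patches = 10L, seed = 8L, val_fraction = 0.2)
  model <- tiny_unet(depth = 1L, base = 4L, seed = 1L)
  fit <- train_unet(model, ds, train_config(epochs = 4L, batch_size = 4L,
                                            lr = 0.01, class_weights = "inverse",
                                            seed = 3L))
  expect_lt(tail(fit$history$val_loss, 1L), fit$history$val_loss[1L])
  # learning curves are recorded per epoch, including epoch 0
  expect_equal(fit$history$epoch, 0:4)
  # fixed seed + fixed data: identical learning curves
  fit2 <- train_unet(model, ds, train_config(epochs = 4L, batch_size = 4L,
                                             lr = 0.01, class_weights = "inverse",
                                             seed = 3L))
  expect_identical(fit$history, fit2$history)
})

test_that("episodic training interleaves datasets and guards the contracts", {
  ds1 <- mosaic_dataset(n_patches = 6L, seed = 1L, val_fraction = 0)
  ds2 <- mosaic_dataset(n_patches = 4L, seed = 2L, val_fraction = 0)
  model <- tiny_unet(depth = 1L, base = 2L, seed = 2L)
  fit <- train_unet(model, list(ds1, ds2),
                    train_config(epochs = 1L, batch_size = 2L, mode = "episodic",
                                 seed = 1L))
  expect_s3_class(fit$model, "seg_model")
  expect_error(train_unet(model, ds1, train_config(mode = "episodic")),
               "two datasets")
  m3 <- tiny_unet(depth = 1L, base = 2L, n_classes = 3L)
  expect_error(train_unet(m3, ds1, train_config(epochs = 1L)), "classes")
  expect_error(train_config(leaky_factor = 0), "leaky_factor")
})
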