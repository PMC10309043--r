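# Scripted experiments built from the pipeline stages: the
# augmentation-comparison harness (train networks under augmentation
# variants, segment held-out images, score with variation of information)
# and the transfer-learning epoch comparison.

#' Concatenate patch datasets
#'
#' Merges datasets built from different source images (e.g. several
#' annotated sections of one specimen) into one training dataset. The
#' configurations must agree on patch size and class count; the first
#' dataset's preprocessing parameters are retained.
#'
#' @param datasets list of `patch_dataset` objects.
#' @return A single `patch_dataset`.
#' @export
merge_patch_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  base <- datasets[[1L]]
  for (ds in datasets[-1L]) {
    if (ds$config$patch_size != base$config$patch_size ||
        ds$config$n_classes != base$config$n_classes)
      stopf("datasets disagree on patch size or class count")
  }
  base$em <- do.call(c, lapply(datasets, `[[`, "em"))
  base$labels <- do.call(c, lapply(datasets, `[[`, "labels"))
  mans <- lapply(datasets, `[[`, "manifest")
  man <- do.call(rbind, mans)
  man$patch <- seq_len(nrow(man))
  base$manifest <- man
  base
}

# Build a membrane/intracellular patch dataset from one mosaic spec.
mosaic_patch_dataset <- function(spec, n_patches, seed,
                                 augmentations = character(),
                                 patch_size = 128L) {
  fx <- generate_mosaic(spec)
  extract_patches(fx$em, matrix(ifelse(fx$membrane, 1L, 0L), nrow(fx$em)),
                  patch_config(patch_size = patch_size, n_patches = n_patches,
                               augmentations = augmentations, seed = seed))
}

first_epoch_reaching <- function(history, threshold) {
  hit <- which(history$val_bacc >= threshold)
  if (length(hit) == 0L) Inf else history$epoch[hit[1L]]
}

#' Transfer-learning epoch comparison on synthetic domains
#'
#' Pretrains a small U-net on mosaics of domain A, then for each seed
#' fine-tunes it (continuous learning) on patches from three domain-B
#' images and trains an identical network from scratch on the same data,
#' recording the first epoch at which each reaches the balanced
#' validation-accuracy threshold. Mirrors, on synthetic data, the
#' observation that continuous learning from a pretrained network needs
#' far fewer epochs than training from scratch.
#'
#' @param seeds seeds for the per-seed fine-tune/scratch comparisons.
#' @param threshold balanced validation accuracy to reach.
#' @param epochs training epochs per run.
#' @param n_pretrain,n_per_image patches for pretraining / per domain-B
#'   image (three images are used).
#' @param spec_a domain-A [mosaic_spec()].
#' @param spec_b function(seed) giving domain-B specs.
#' @param cfg a [unet_config()] for the (small) networks.
#' @return List: per-seed data frame (`seed`, `epochs_finetune`,
#'   `epochs_scratch`) and `wins` (seeds where fine-tuning was strictly
#'   faster).
#' @export
transfer_experiment <- function(seeds = 1:5, threshold = 0.85, epochs = 6L,
                                n_pretrain = 40L, n_per_image = 10L,
                                spec_a = mosaic_spec(size = 256, cells = 12, seed = 21),
                                spec_b = function(seed)
                                  mosaic_spec(size = 256, cells = 10,
                                              gray_intra = 120, gray_membrane = 30,
                                              noise_sd = 14, blur_sigma = 1.5,
                                              seed = seed),
                                cfg = unet_config(depth = 1L, base_channels = 4L,
                                                  n_classes = 2L)) {
  ds_a <- mosaic_patch_dataset(spec_a, n_pretrain, seed = 1L)
  pre <- train_unet(build_unet(cfg, seed = 3L), ds_a,
                    train_config(epochs = epochs, lr = 0.01,
                                 class_weights = "inverse", seed = 4L))
  rows <- lapply(seeds, function(seed) {
    parts <- lapply(1:3, function(k)
      mosaic_patch_dataset(spec_b(100L + 10L * seed + k), n_per_image, seed = seed))
    ds_b <- merge_patch_datasets(parts)
    ft <- train_unet(pre$model, ds_b,
                     train_config(epochs = epochs, lr = 0.01, mode = "continuous",
                                  class_weights = "inverse", seed = seed))
    sc <- train_unet(build_unet(cfg, seed = seed), ds_b,
                     train_config(epochs = epochs, lr = 0.01,
                                  class_weights = "inverse", seed = seed))
    data.frame(seed = seed,
               epochs_finetune = first_epoch_reaching(ft$history, threshold),
               epochs_scratch = first_epoch_reaching(sc$history, threshold))
  })
  res <- do.call(rbind, rows)
  list(per_seed = res,
       wins = sum(res$epochs_finetune < res$epochs_scratch),
       threshold = threshold)
}

#' Augmentation-comparison harness (test variation of information)
#'
#' Trains one network per augmentation variant on patches from a training
#' mosaic, segments held-out test mosaics end to end (prediction,
#' watershed expansion), and scores each against the instance ground
#' truth with variation of information. Reports the mean test VI with the
#' standard error over test images, and optionally over reseeded
#' retrainings.
#'
#' @param variants named list of augmentation-id vectors (subsets of
#'   [EMSEG_AUGMENTATIONS]).
#' @param n_test held-out test mosaics.
#' @param retrain_seeds training seeds per variant.
#' @param n_patches training patches per run.
#' @param epochs training epochs.
#' @param cfg a [unet_config()].
#' @return Data frame: variant, mean VI, SEM over test images, SEM over
#'   retrainings.
#' @export
augmentation_benchmark <- function(variants = list(none = character(),
                                                   flip = "flip"),
                                   n_test = 6L, retrain_seeds = 1:2,
                                   n_patches = 40L, epochs = 6L,
                                   cfg = unet_config(depth = 1L,
                                                     base_channels = 4L,
                                                     n_classes = 2L)) {
  train_spec <- mosaic_spec(size = 256, cells = 12, seed = 31)
  tests <- lapply(seq_len(n_test), function(k)
    generate_mosaic(mosaic_spec(size = 256, cells = 12, seed = 500L + k)))
  rows <- lapply(names(variants), function(vn) {
    vi_mat <- sapply(retrain_seeds, function(seed) {
      ds <- mosaic_patch_dataset(train_spec, n_patches, seed = seed,
                                 augmentations = variants[[vn]])
      fit <- train_unet(build_unet(cfg, seed = seed), ds,
                        train_config(epochs = epochs, lr = 0.01,
                                     class_weights = "inverse", seed = seed))
      vapply(tests, function(fx) {
        prob <- predict_unet(fit$model, fx$em, ds$preprocess)
        inst <- expand_watershed(prob[, , 2L], expansion_params())
        variation_of_information(fx$instances, inst)$vi
      }, numeric(1))
    })
    per_image <- rowMeans(vi_mat)
    per_seed <- colMeans(vi_mat)
    data.frame(variant = vn, mean_vi = mean(vi_mat),
               sem_images = stats::sd(per_image) / sqrt(length(per_image)),
               sem_retrain = if (length(per_seed) > 1L)
                 stats::sd(per_seed) / sqrt(length(per_seed)) else NA_real_)
  })
  do.call(rbind, rows)
}
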