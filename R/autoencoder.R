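#' Extract random patches from a volume
#'
#' Samples `n` patch corner positions uniformly (with replacement) over all
#' positions at which a `patch_shape` sub-volume fits, and returns the
#' stacked patches. The default reproduces the pretraining regime of 20000
#' patches of 25 x 25 x 4 voxels per volume.
#'
#' @param volume 3D array, at least `patch_shape` along every axis.
#' @param patch_shape Integer patch shape `(height, width, depth)`.
#' @param n Number of patches to draw.
#' @param seed Integer seed; identical seeds reproduce identical patch sets.
#' @return An object of class `patch_set`: a list with `patches` (4D array
#'   `(ph, pw, pd, n)`), `corners` (tibble of 1-based `y`, `x`, `z` corner
#'   indices), `patch_shape`, and `seed`.
#' @export
extract_patches <- function(volume, patch_shape = c(25L, 25L, 4L),
                            n = 20000L, seed = 1L) {
  check_volume(volume)
  patch_shape <- as.integer(patch_shape)
  d <- dim(volume)
  if (any(d < patch_shape))
    stop_shape(sprintf("volume of shape %s is smaller than patch shape %s",
                       fmt_shape(d), fmt_shape(patch_shape)))
  check_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  valid <- d - patch_shape + 1L
  with_seed_local(seed, {
    ys <- sample.int(valid[1], n, replace = TRUE)
    xs <- sample.int(valid[2], n, replace = TRUE)
    zs <- sample.int(valid[3], n, replace = TRUE)
  })
  patches <- array(0, dim = c(patch_shape, n))
  for (i in seq_len(n)) {
    patches[, , , i] <- volume[ys[i]:(ys[i] + patch_shape[1] - 1L),
                               xs[i]:(xs[i] + patch_shape[2] - 1L),
                               zs[i]:(zs[i] + patch_shape[3] - 1L)]
  }
  structure(list(patches = patches,
                 corners = tibble(y = ys, x = xs, z = zs),
                 patch_shape = patch_shape,
                 seed = as.integer(seed)),
            class = "patch_set")
}

#' Extract patches from a corpus of volumes
#'
#' Convenience wrapper drawing `n_per_volume` patches from each corpus
#' volume (per-volume seeds derived from `seed`) and concatenating them
#' into one `patch_set`.
#'
#' @param corpus Tibble with a `volume` list-column (see
#'   [generate_source_corpus()]), or a list of 3D arrays.
#' @param patch_shape Integer patch shape.
#' @param n_per_volume Patches drawn per volume.
#' @param seed Integer master seed.
#' @return A `patch_set` whose `source` field records the volume index of
#'   each patch.
#' @export
extract_corpus_patches <- function(corpus, patch_shape = c(25L, 25L, 4L),
                                   n_per_volume = 20000L, seed = 1L) {
  vols <- as_volume_list(corpus, "corpus")
  sets <- lapply(seq_along(vols), function(i)
    extract_patches(vols[[i]], patch_shape, n_per_volume,
                    seed = derive_seed(seed, 5L, i)))
  patches <- array(0, dim = c(as.integer(patch_shape),
                              length(vols) * as.integer(n_per_volume)))
  for (i in seq_along(sets)) {
    idx <- (i - 1L) * n_per_volume + seq_len(n_per_volume)
    patches[, , , idx] <- sets[[i]]$patches
  }
  structure(list(patches = patches,
                 corners = dplyr::bind_rows(lapply(sets, `[[`, "corners")),
                 source = rep(seq_along(vols), each = n_per_volume),
                 patch_shape = as.integer(patch_shape),
                 seed = as.integer(seed)),
            class = "patch_set")
}

#' Initialize an untrained autoencoder
#'
#' Builds the encoder/decoder weight tensors with seeded random
#' initialization and no training. Useful as the baseline when measuring
#' what pretraining adds.
#'
#' @param config An [autoencoder_config()] object.
#' @param patch_shape Patch shape the autoencoder will consume.
#' @return An object of class `encoder_weights` with `final_loss = NA`.
#' @export
init_autoencoder <- function(config = autoencoder_config(),
                             patch_shape = c(25L, 25L, 4L)) {
  stopifnot(inherits(config, "autoencoder_config"))
  params <- with_seed_local(config$seed, ae_init_params(config))
  new_encoder_weights(params, config, as.integer(patch_shape),
                      final_loss = NA_real_, history = NULL)
}

new_encoder_weights <- function(params, config, patch_shape, final_loss, history) {
  L <- length(config$encoder_filters)
  layers <- lapply(seq_len(L), function(i)
    list(layer_index = i,
         kernel = params[[sprintf("enc%d.W", i)]],
         bias = params[[sprintf("enc%d.b", i)]]))
  structure(list(layers = layers,
                 decoder = lapply(seq_len(L), function(i)
                   list(layer_index = i,
                        kernel = params[[sprintf("dec%d.W", i)]],
                        bias = params[[sprintf("dec%d.b", i)]])),
                 config = config,
                 patch_shape = patch_shape,
                 final_loss = final_loss,
                 history = history),
            class = "encoder_weights")
}

encoder_weights_params <- function(w) {
  params <- list()
  for (l in w$layers) {
    params[[sprintf("enc%d.W", l$layer_index)]] <- l$kernel
    params[[sprintf("enc%d.b", l$layer_index)]] <- l$bias
  }
  for (l in w$decoder) {
    params[[sprintf("dec%d.W", l$layer_index)]] <- l$kernel
    params[[sprintf("dec%d.b", l$layer_index)]] <- l$bias
  }
  params
}

#' Pretrain the patch autoencoder
#'
#' Trains the convolutional autoencoder to reconstruct patches by mean
#' squared error with Adam, then exports the encoder weights (ordered layer
#' records of 3x3x3 kernels and biases) for transfer into the classifier.
#' The decoder is retained in the returned object so reconstruction error
#' can still be evaluated.
#'
#' @param patches A `patch_set` from [extract_patches()] or
#'   [extract_corpus_patches()].
#' @param config An [autoencoder_config()] object.
#' @return An object of class `encoder_weights` carrying the per-layer
#'   encoder kernels/biases, the mirrored decoder, the config, the final
#'   epoch's mean reconstruction loss, and the per-epoch loss history.
#' @export
train_autoencoder <- function(patches, config = autoencoder_config()) {
  stopifnot(inherits(patches, "patch_set"), inherits(config, "autoencoder_config"))
  n <- dim(patches$patches)[4]
  if (is.na(n) || n < 1L) stop_input("`patches` is empty")
  ps <- patches$patch_shape
  if (any(ps < 3L))
    stop_config(sprintf("patch shape %s is below the 3x3x3 receptive field",
                        fmt_shape(ps)))
  with_seed_local(config$seed, {
    params <- ae_init_params(config)
    state <- adam_init(params)
    t_step <- 0
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        x_mat <- matrix(as.numeric(patches$patches[, , , b, drop = FALSE]),
                        ncol = 1)
        fw <- ae_forward(params, config, ps, x_mat, length(b),
                         keep_cache = TRUE)
        grads <- ae_backward(params, config, ps, fw$cache, x_mat)
        ep_loss <- ep_loss + sum((fw$xhat - x_mat)^2) / prod(ps)
        grads <- lapply(grads, `/`, length(b))
        t_step <- t_step + 1
        upd <- adam_step(params, grads, state, config$learning_rate, t_step)
        params <- upd$params; state <- upd$state
      }
      history[epoch] <- ep_loss / n
    }
  })
  new_encoder_weights(params, config, ps,
                      final_loss = history[config$epochs],
                      history = tibble(epoch = seq_len(config$epochs),
                                       reconstruction_mse = history))
}

#' Mean squared reconstruction error of an autoencoder on patches
#'
#' @param weights An `encoder_weights` object (trained or untrained).
#' @param patches A `patch_set` with the same patch shape.
#' @return Nonnegative scalar: the mean squared error per voxel over all
#'   patches (equal to the mean of per-patch errors).
#' @export
reconstruction_error <- function(weights, patches) {
  stopifnot(inherits(weights, "encoder_weights"), inherits(patches, "patch_set"))
  if (!all(patches$patch_shape == weights$patch_shape))
    stop_shape(sprintf("patch shape %s does not match autoencoder patch shape %s",
                       fmt_shape(patches$patch_shape), fmt_shape(weights$patch_shape)))
  params <- encoder_weights_params(weights)
  ps <- patches$patch_shape
  n <- dim(patches$patches)[4]
  total <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / 64))) {
    x_mat <- matrix(as.numeric(patches$patches[, , , b, drop = FALSE]), ncol = 1)
    fw <- ae_forward(params, weights$config, ps, x_mat, length(b))
    total <- total + sum((fw$xhat - x_mat)^2) / prod(ps)
  }
  total / n
}
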