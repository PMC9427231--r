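# Shared fixtures: small, fast synthetic inputs built in code.

# default-ish phantom parameters at reduced size for fast tests
small_params <- function(shape = c(16, 16, 8), noise_sigma = 0.05, seed = 1L,
                         lesion_radius_range = c(1.5, 2.5), ...) {
  phantom_params(shape = shape, lesion_radius_range = lesion_radius_range,
                 noise_sigma = noise_sigma, seed = seed, ...)
}

# a tiny labeled dataset of hand-made volumes for harness bookkeeping tests:
# class 1 volumes carry a bright 3x3x3 block at a jittered position
toy_dataset <- function(n_per_class = 3, shape = c(10, 10, 6), seed = 1) {
  phantomnet:::with_seed_local(seed, {
    vols <- list(); labels <- integer()
    for (i in seq_len(2 * n_per_class)) {
      lab <- as.integer(i > n_per_class)
      v <- array(rnorm(prod(shape), mean = 0.3, sd = 0.05), dim = shape)
      if (lab == 1L) {
        cy <- sample(2:(shape[1] - 2), 1); cx <- sample(2:(shape[2] - 2), 1)
        cz <- sample(2:(shape[3] - 1), 1)
        v[cy + (-1:1), cx + (-1:1), cz + (-1:1)] <- 0.9
      }
      vols[[i]] <- v; labels[i] <- lab
    }
    tibble::tibble(id = sprintf("toy%02d", seq_along(vols)),
                   label = labels, volume = vols)
  })
}

# a delta volume: background `bg` with one bright voxel
delta_volume <- function(shape = c(21, 21, 3), at = c(11, 11, 2), value = 1) {
  v <- array(0, dim = shape)
  v[at[1], at[2], at[3]] <- value
  v
}

fast_classifier_config <- function(epochs = 3L, ...) {
  classifier_config(n_conv_layers = 1L, filters = 16L, fc_nodes = 16L,
                    epochs = epochs, batch_size = 8L, ...)
}
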