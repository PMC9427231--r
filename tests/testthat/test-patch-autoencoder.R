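test_that("extract_patches honors count, shape, bounds and the recorded corners", {
  v <- array(rnorm(30 * 28 * 6), dim = c(30, 28, 6))
  ps <- extract_patches(v, patch_shape = c(25, 25, 4), n = 40, seed = 2)
  expect_equal(dim(ps$patches), c(25, 25, 4, 40))
  expect_true(all(ps$corners$y >= 1 & ps$corners$y <= 30 - 25 + 1))
  expect_true(all(ps$corners$x >= 1 & ps$corners$x <= 28 - 25 + 1))
  expect_true(all(ps$corners$z >= 1 & ps$corners$z <= 6 - 4 + 1))
  # each patch equals the slice at its recorded corner
  for (i in c(1, 17, 40)) {
    cr <- ps$corners[i, ]
    expect_identical(ps$patches[, , , i],
                     v[cr$y:(cr$y + 24), cr$x:(cr$x + 24), cr$z:(cr$z + 3)])
  }
  # determinism
  expect_identical(ps$patches, extract_patches(v, c(25, 25, 4), 40, seed = 2)$patches)

  # single valid position: all patches equal the volume
  v2 <- array(rnorm(25 * 25 * 4), dim = c(25, 25, 4))
  ps2 <- extract_patches(v2, n = 5, seed = 1)
  for (i in 1:5) expect_identical(ps2$patches[, , , i], v2)

  expect_error(extract_patches(array(0, dim = c(10, 10, 4)), c(25, 25, 4), 5),
               "10x10x4", class = "phantomnet_shape_error")
})

test_that("autoencoder training reduces reconstruction loss and is seed-deterministic", {
  set.seed(3)
  v <- array(runif(30 * 30 * 6), dim = c(30, 30, 6))
  ps <- extract_patches(v, patch_shape = c(8, 8, 4), n = 64, seed = 4)
  cfg <- autoencoder_config(encoder_filters = 16L, epochs = 4, batch_size = 16,
                            seed = 9)
  w <- train_autoencoder(ps, cfg)
  expect_s3_class(w, "encoder_weights")
  expect_lt(w$final_loss, w$history$reconstruction_mse[1])
  expect_equal(w$final_loss, dplyr::last(w$history$reconstruction_mse))

  w2 <- train_autoencoder(ps, cfg)
  expect_identical(w$layers, w2$layers)
})

test_that("reconstruction loss trends down across seeds (final <= first epoch)", {
  set.seed(6)
  v <- array(runif(20 * 20 * 6), dim = c(20, 20, 6))
  ps <- extract_patches(v, patch_shape = c(8, 8, 4), n = 48, seed = 1)
  failures <- 0L
  for (s in 1:10) {
    cfg <- autoencoder_config(encoder_filters = 16L, epochs = 3,
                              batch_size = 16, seed = s)
    w <- train_autoencoder(ps, cfg)
    if (w$history$reconstruction_mse[3] > w$history$reconstruction_mse[1])
      failures <- failures + 1L
  }
  expect_lte(failures, 1L)
})

test_that("pretraining beats a random encoder on held-out patches", {
  p <- small_params(shape = c(30, 30, 8), noise_sigma = 0.05, seed = 21)
  corpus <- generate_source_corpus(4, p)
  train_ps <- extract_corpus_patches(corpus, patch_shape = c(10, 10, 4),
                                     n_per_volume = 60, seed = 5)
  held <- extract_patches(generate_source_corpus(1, small_params(
    shape = c(30, 30, 8), noise_sigma = 0.05, seed = 99))$volume[[1]],
    patch_shape = c(10, 10, 4), n = 50, seed = 6)
  cfg <- autoencoder_config(encoder_filters = 16L, epochs = 5, batch_size = 32,
                            seed = 2)
  trained <- train_autoencoder(train_ps, cfg)
  untrained <- init_autoencoder(cfg, patch_shape = c(10, 10, 4))
  expect_lt(reconstruction_error(trained, held),
            reconstruction_error(untrained, held))
})

test_that("reconstruction_error matches a brute-force sum-of-squares oracle", {
  cfg <- autoencoder_config(encoder_filters = 16L, seed = 7)
  w <- init_autoencoder(cfg, patch_shape = c(6, 6, 4))
  set.seed(8)
  patches <- array(rnorm(6 * 6 * 4 * 3), dim = c(6, 6, 4, 3))
  ps <- structure(list(patches = patches, patch_shape = c(6L, 6L, 4L),
                       corners = NULL, seed = 8L), class = "patch_set")
  err <- reconstruction_error(w, ps)
  # oracle: reconstruct each patch independently and average voxel MSEs
  params <- phantomnet:::encoder_weights_params(w)
  per <- vapply(1:3, function(i) {
    x <- matrix(as.numeric(patches[, , , i]), ncol = 1)
    xh <- phantomnet:::ae_forward(params, cfg, c(6L, 6L, 4L), x, 1L)$xhat
    mean((xh - x)^2)
  }, numeric(1))
  expect_equal(err, mean(per))
  expect_gte(err, 0)

  bad <- structure(list(patches = array(0, c(5, 5, 4, 2)),
                        patch_shape = c(5L, 5L, 4L)), class = "patch_set")
  expect_error(reconstruction_error(w, bad), class = "phantomnet_shape_error")
})

test_that("encoder/decoder mirror symmetry holds for all configured depths", {
  for (filt in list(16L, c(16L, 32L), c(16L, 32L, 64L))) {
    cfg <- autoencoder_config(encoder_filters = filt, seed = 1)
    w <- init_autoencoder(cfg, patch_shape = c(8, 8, 4))
    L <- length(filt)
    for (i in seq_len(L)) {
      enc_out <- dim(w$layers[[i]]$kernel)[5]
      dec_in <- dim(w$decoder[[L - i + 1]]$kernel)[4]
      expect_equal(dec_in, enc_out)
    }
    expect_equal(dim(w$decoder[[L]]$kernel)[5], 1L)  # reconstructs intensities
  }
})
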