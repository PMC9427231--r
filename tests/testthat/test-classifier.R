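test_that("built classifiers emit sigmoid probabilities and seeded initial weights", {
  cfg <- classifier_config(n_conv_layers = 2, filters = 32, fc_nodes = 16, seed = 5)
  shp <- c(12L, 12L, 6L)
  m <- build_classifier(cfg, shp)
  x <- array(rnorm(prod(shp)), shp)
  p <- phantomnet:::classifier_forward(m$params, cfg, shp, x)$p
  expect_true(p >= 0 && p <= 1)

  m2 <- build_classifier(cfg, shp)
  expect_identical(m$params, m2$params)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(build_classifier(cfg2, shp)$params, m$params))
})

test_that("parameter counts follow the architecture formula and shrink with fc_nodes", {
  shp <- c(10L, 10L, 4L)
  count_oracle <- function(layers, filters, fc) {
    cin <- 1; n <- 0
    for (i in seq_len(layers)) { n <- n + 27 * cin * filters + filters; cin <- filters }
    nflat <- prod(shp) * cin
    n + nflat * fc + fc + fc + 1
  }
  for (layers in 1:3) for (fc in c(16L, 64L)) {
    cfg <- classifier_config(n_conv_layers = layers, filters = 32, fc_nodes = fc)
    expect_equal(n_parameters(build_classifier(cfg, shp)),
                 count_oracle(layers, 32, fc))
  }
  n16 <- n_parameters(build_classifier(
    classifier_config(n_conv_layers = 2, filters = 32, fc_nodes = 16), shp))
  n64 <- n_parameters(build_classifier(
    classifier_config(n_conv_layers = 2, filters = 32, fc_nodes = 64), shp))
  expect_lt(n16, n64)
})

test_that("encoder transfer copies matching prefixes bitwise and leaves the rest alone", {
  ae_cfg <- autoencoder_config(encoder_filters = c(16L, 32L, 64L), seed = 3)
  w <- init_autoencoder(ae_cfg, patch_shape = c(8, 8, 4))
  shp <- c(10L, 10L, 4L)

  # exact-shape transfer: all three conv layers bitwise equal
  cfg3 <- classifier_config(n_conv_layers = 3, filters = c(16L, 32L, 64L),
                            fc_nodes = 16, seed = 9)
  m3 <- build_classifier(cfg3, shp)
  t3 <- initialize_from_encoder(m3, w)
  for (i in 1:3) {
    expect_identical(t3$params[[sprintf("conv%d.W", i)]], w$layers[[i]]$kernel)
    expect_identical(t3$params[[sprintf("conv%d.b", i)]], w$layers[[i]]$bias)
  }
  expect_identical(t3$params$fc.W, m3$params$fc.W)
  expect_identical(t3$params$fc.b, m3$params$fc.b)
  expect_identical(t3$params$out.W, m3$params$out.W)
  expect_identical(t3$init_mode, "transfer")

  # prefix rule: 1-layer classifier takes encoder layer 1 only
  cfg1 <- classifier_config(n_conv_layers = 1, filters = 16, fc_nodes = 16, seed = 9)
  m1 <- build_classifier(cfg1, shp)
  t1 <- initialize_from_encoder(m1, w)
  expect_identical(t1$params$conv1.W, w$layers[[1]]$kernel)

  # filter-count mismatch: leading sub-tensor copied, remainder random
  cfg_mis <- classifier_config(n_conv_layers = 1, filters = 32, fc_nodes = 16, seed = 9)
  mm <- build_classifier(cfg_mis, shp)
  tm <- initialize_from_encoder(mm, w)
  expect_identical(tm$params$conv1.W[, , , , 1:16], w$layers[[1]]$kernel[, , , , 1:16])
  expect_identical(tm$params$conv1.W[, , , , 17:32], mm$params$conv1.W[, , , , 17:32])
})

test_that("predictions carry the threshold, tie and confidence-disparity rules", {
  mk <- function(p) tibble::tibble(probability = p,
                                   label = as.integer(p >= 0.5),
                                   confidence = abs(2 * p - 1))
  # the documented arithmetic
  expect_equal(mk(0.9)$label, 1L)
  expect_equal(mk(0.9)$confidence, 0.8)
  expect_equal(mk(0.1)$label, 0L)
  expect_equal(mk(0.1)$confidence, 0.8)
  expect_equal(mk(0.5)$label, 1L)   # tie maps to class 1
  expect_equal(mk(0.5)$confidence, 0)
  # symmetry of the disparity score
  for (p in seq(0, 1, by = 0.05)) {
    expect_equal(abs(2 * p - 1), abs(2 * (1 - p) - 1))
  }
})

test_that("training checkpoints the best validation epoch and improves the loss", {
  d <- toy_dataset(n_per_class = 6, shape = c(10, 10, 6), seed = 2)
  cfg <- classifier_config(n_conv_layers = 1, filters = 16, fc_nodes = 16,
                           epochs = 5, batch_size = 8, seed = 13)
  m <- build_classifier(cfg, c(10L, 10L, 6L))
  fit <- train_classifier(m, d)
  expect_equal(nrow(fit$history), 5)
  expect_true(fit$checkpoint_epoch >= 1 && fit$checkpoint_epoch <= 5)
  expect_equal(fit$best_val_accuracy, max(fit$history$val_accuracy))
  # ties break toward the earliest epoch
  expect_equal(fit$checkpoint_epoch,
               which.max(fit$history$val_accuracy))
  expect_lte(fit$history$train_loss[fit$checkpoint_epoch] * 0.999,
             fit$history$train_loss[1] + 1e-9)

  pr <- predict(fit, d$volume[[1]])
  expect_true(pr$probability >= 0 && pr$probability <= 1)
  expect_equal(pr$confidence, abs(2 * pr$probability - 1))
  expect_error(predict(fit, array(0, dim = c(4, 4, 4))),
               class = "phantomnet_shape_error")
})

test_that("an easily separable fixture reaches high inner-validation accuracy", {
  p <- phantom_params(shape = c(24, 24, 10), lesion_radius_range = c(2, 3),
                      lesion_contrast = 0.5, noise_sigma = 0.02, seed = 71)
  d <- generate_labeled_dataset(10, 10, p)
  wv <- phantomnet:::window_volumes(d$volume, 0.95)
  norm <- fit_normalizer(wv)
  d$volume <- lapply(wv, apply_normalizer, norm = norm)
  hits <- 0L
  for (s in c(3, 4, 5)) {
    cfg <- classifier_config(n_conv_layers = 1, filters = 16, fc_nodes = 16,
                             epochs = 15, batch_size = 8, seed = s)
    fit <- train_classifier(build_classifier(cfg, p$shape), d)
    if (fit$best_val_accuracy >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("training is deterministic under a fixed seed and rejects single-class folds", {
  d <- toy_dataset(n_per_class = 4, shape = c(10, 10, 6), seed = 5)
  cfg <- fast_classifier_config(seed = 21)
  m <- build_classifier(cfg, c(10L, 10L, 6L))
  f1 <- train_classifier(m, d)
  f2 <- train_classifier(m, d)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)

  single <- dplyr::filter(d, label == 0)
  expect_error(train_classifier(m, single), class = "phantomnet_config_error")
})
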