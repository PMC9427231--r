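test_that("confusion_metrics matches hand-computed tables and flags undefined ratios", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(as.numeric(m[, c("tp", "fp", "tn", "fn")]), c(1, 0, 2, 1))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)

  all_right <- confusion_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(c(all_right$accuracy, all_right$sensitivity, all_right$specificity),
               c(1, 1, 1))

  none_pos <- confusion_metrics(c(0, 0, 0), c(0, 1, 0))
  expect_true(is.nan(none_pos$sensitivity))
  expect_false(is.nan(none_pos$specificity))

  expect_error(confusion_metrics(c(0, 1), c(1)), class = "phantomnet_input_error")
})

test_that("metrics agree with a brute-force confusion oracle on random vectors", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    y <- rbinom(n, 1, 0.5); yh <- rbinom(n, 1, 0.5)
    m <- confusion_metrics(y, yh)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (y[j] == 1 && yh[j] == 1) tp <- tp + 1
      if (y[j] == 0 && yh[j] == 1) fp <- fp + 1
      if (y[j] == 0 && yh[j] == 0) tn <- tn + 1
      if (y[j] == 1 && yh[j] == 0) fn <- fn + 1
    }
    expect_equal(as.numeric(m[, c("tp", "fp", "tn", "fn")]), c(tp, fp, tn, fn))
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
  }
})

test_that("LOOCV produces one fold per sample with leakage-free normalizers", {
  d <- toy_dataset(n_per_class = 3, shape = c(10, 10, 6), seed = 31)
  cfg <- fast_classifier_config(epochs = 2L)
  cv <- run_loocv(d, cfg, seed = 5)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$predictions), 6)
  expect_identical(cv$predictions$fold, 1:6)
  expect_identical(cv$predictions$label, d$label)
  expect_true(all(cv$predictions$pred_label %in% 0:1))

  # per-fold normalizer differs from the all-data normalizer
  wv <- phantomnet:::window_volumes(d$volume, 0.95)
  n_fold1 <- fit_normalizer(wv[-1])
  n_all <- fit_normalizer(wv)
  expect_false(identical(n_fold1$train_mean, n_all$train_mean))

  expect_error(run_loocv(d[1:3, ], cfg), class = "phantomnet_config_error")
  expect_error(run_loocv(dplyr::filter(d, label == 0), cfg),
               class = "phantomnet_config_error")
})

test_that("LOOCV is deterministic under the master seed", {
  d <- toy_dataset(n_per_class = 2, shape = c(8, 8, 4), seed = 13)
  cfg <- fast_classifier_config(epochs = 2L)
  cv1 <- run_loocv(d, cfg, seed = 42)
  cv2 <- run_loocv(d, cfg, seed = 42)
  expect_identical(cv1$predictions, cv2$predictions)
  cv3 <- run_loocv(d, cfg, seed = 43)
  expect_false(identical(cv1$predictions$probability, cv3$predictions$probability))
})

test_that("grid search performs repeats x configs LOOCVs and summarizes ranges", {
  d <- toy_dataset(n_per_class = 3, shape = c(8, 8, 4), seed = 3)
  g <- hyperparameter_grid()
  expect_equal(nrow(g), 9)
  expect_identical(unique(g$n_conv_layers), 1:3)
  expect_equal(nrow(hyperparameter_grid(full = TRUE)), 27)

  gs <- run_grid_search(d, grid = g[1:2, ], repeats = 2,
                        base_config = fast_classifier_config(epochs = 2L),
                        seed = 8)
  expect_equal(nrow(gs$runs), 4)  # 2 configs x 2 repeats
  expect_true(all(vapply(gs$runs$cv, function(cv) nrow(cv$predictions), numeric(1)) == 6))
  expect_equal(nrow(gs$summary), 2)
  for (met in c("accuracy", "sensitivity", "specificity")) {
    expect_true(all(gs$summary[[paste0(met, "_min")]] <=
                    gs$summary[[paste0(met, "_mean")]] + 1e-12))
    expect_true(all(gs$summary[[paste0(met, "_mean")]] <=
                    gs$summary[[paste0(met, "_max")]] + 1e-12))
  }
  expect_equal(nrow(gs$best), 1)
  expect_equal(gs$best$accuracy_mean, max(gs$summary$accuracy_mean))

  # determinism of the whole procedure
  gs2 <- run_grid_search(d, grid = g[1:2, ], repeats = 2,
                         base_config = fast_classifier_config(epochs = 2L),
                         seed = 8)
  expect_identical(dplyr::select(gs$runs, -"cv"), dplyr::select(gs2$runs, -"cv"))
})

test_that("triage curves rank by confidence and recover overall accuracy at full coverage", {
  cv <- structure(list(
    predictions = tibble::tibble(
      fold = 1:4, id = letters[1:4], label = c(1L, 0L, 1L, 0L),
      probability = c(0.95, 0.4, 0.3, 0.45),
      pred_label = c(1L, 0L, 0L, 0L),
      confidence = c(0.9, 0.2, 0.4, 0.1)),
    metrics = confusion_metrics(c(1, 0, 1, 0), c(1, 0, 0, 0))),
    class = "cv_result")
  tc <- triage_curve(cv, coverages = c(0.25, 0.5, 0.75, 1.0))
  expect_equal(tc$n, c(1L, 2L, 3L, 4L))
  # most confident first: folds 1 (right), 3 (wrong), 2 (right), 4 (right)
  expect_equal(tc$accuracy, c(1, 1/2, 2/3, 3/4))
  expect_equal(tc$accuracy[4], cv$metrics$accuracy)

  # top-1 selection: confident-and-right beats unconfident-and-wrong
  cv2 <- cv
  cv2$predictions$confidence <- c(0.9, 0.1, 0.1, 0.1)
  expect_equal(triage_curve(cv2, coverages = 0.5)$accuracy, 1)

  expect_error(triage_curve(cv, coverages = c(0, 0.5)),
               class = "phantomnet_param_error")
  expect_error(triage_curve(cv, coverages = 1.2),
               class = "phantomnet_param_error")
})

test_that("confidence ranking is calibrated: half-coverage accuracy is rarely below full", {
  p <- phantom_params(shape = c(16, 16, 8), lesion_radius_range = c(1.5, 2.5),
                      lesion_contrast = 0.5, noise_sigma = 0.02, seed = 81)
  d <- generate_labeled_dataset(5, 5, p)
  cfg <- classifier_config(n_conv_layers = 1, filters = 16, fc_nodes = 16,
                           epochs = 4, batch_size = 8)
  failures <- 0L
  for (s in 1:10) {
    cv <- run_loocv(d, cfg, seed = s)
    tc <- triage_curve(cv, coverages = c(0.5, 1.0))
    if (tc$accuracy[1] < tc$accuracy[2]) failures <- failures + 1L
  }
  expect_lte(failures, 2L)
})

test_that("initialization comparison pairs seeds and averages per-seed differences", {
  d <- toy_dataset(n_per_class = 2, shape = c(8, 8, 4), seed = 17)
  ae_cfg <- autoencoder_config(encoder_filters = 16L, seed = 2)
  w <- init_autoencoder(ae_cfg, patch_shape = c(8, 8, 4))
  cmp <- compare_initializations(d, fast_classifier_config(epochs = 2L),
                                 weights = w, n_seeds = 2, seed = 6)
  expect_s3_class(cmp, "init_comparison")
  expect_equal(nrow(cmp$per_seed), 2)
  expect_equal(cmp$summary$mean_improvement_pp,
               mean(cmp$per_seed$improvement_pp))
  expect_equal(cmp$per_seed$improvement_pp,
               100 * (cmp$per_seed$accuracy_transfer - cmp$per_seed$accuracy_random))
  # paired arms share the derived seed
  for (s in 1:2) {
    expect_identical(cmp$cv_pairs[[s]]$random$seed, cmp$cv_pairs[[s]]$transfer$seed)
    expect_identical(cmp$cv_pairs[[s]]$random$predictions$fold,
                     cmp$cv_pairs[[s]]$transfer$predictions$fold)
  }
})

test_that("tidiers expose predictions, summaries and histories as tibbles", {
  d <- toy_dataset(n_per_class = 2, shape = c(8, 8, 4), seed = 19)
  cv <- run_loocv(d, fast_classifier_config(epochs = 2L), seed = 3)
  expect_identical(tidy(cv), cv$predictions)
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("accuracy", "init_mode", "n_folds") %in% names(gl)))

  tc <- triage_curve(cv, coverages = c(0.5, 1))
  pl <- autoplot(tc)
  expect_s3_class(pl, "ggplot")
})
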