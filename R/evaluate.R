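#' Confusion-matrix classification metrics
#'
#' Computes TP/FP/TN/FN counts and accuracy, sensitivity (true-positive rate
#' among unhealthy samples) and specificity (true-negative rate among
#' healthy samples). Metrics with an undefined denominator are reported as
#' `NaN`, never silently as zero.
#'
#' @param labels Binary vector of true labels (0/1).
#' @param predictions Binary vector of predicted labels, or a prediction
#'   tibble with a `label` column (as returned by [predict.cnn3d_fit()]).
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(labels, predictions) {
  pred <- if (is.data.frame(predictions)) predictions$label else predictions
  if (length(labels) != length(pred))
    stop_input(sprintf("labels (%d) and predictions (%d) differ in length",
                       length(labels), length(pred)))
  if (length(labels) < 1L) stop_input("need at least one prediction")
  labels <- as.integer(labels); pred <- as.integer(pred)
  tp <- sum(labels == 1L & pred == 1L)
  fp <- sum(labels == 0L & pred == 1L)
  tn <- sum(labels == 0L & pred == 0L)
  fn <- sum(labels == 1L & pred == 0L)
  div <- function(a, b) if (b == 0) NaN else a / b
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = div(tp + tn, tp + fp + tn + fn),
         sensitivity = div(tp, tp + fn),
         specificity = div(tn, tn + fp))
}

# Preprocess one LOOCV fold without leakage: per-image windows everywhere,
# normalizer fitted on the training volumes only.
prep_fold <- function(windowed, train_idx, test_idx) {
  norm <- fit_normalizer(windowed[train_idx])
  list(train = lapply(windowed[train_idx], apply_normalizer, norm = norm),
       test = lapply(windowed[test_idx], apply_normalizer, norm = norm),
       norm = norm)
}

#' Leave-one-out cross-validation of the 3D CNN classifier
#'
#' Runs one LOOCV pass: for each sample, hold it out, window every volume
#' with its own intensity window, fit the brightness normalizer on the
#' remaining samples only, train a classifier (randomly or transfer
#' initialized) on them, and predict the held-out sample. Fold seeds derive
#' deterministically from `seed`.
#'
#' @param data Labeled dataset tibble (`volume` list-column, `label` 0/1,
#'   optional `id`); at least 4 samples with both classes present.
#' @param config A [classifier_config()] object (its `seed` is overridden
#'   per fold).
#' @param augment Optional [augmentation_config()] for the inner-training
#'   samples of each fold.
#' @param init `"random"`, or an `encoder_weights` object for transfer
#'   initialization.
#' @param coverage Window coverage fraction used for preprocessing.
#' @param seed Integer master seed for the whole procedure.
#' @return An object of class `cv_result`: per-fold predictions (tibble with
#'   `fold`, `id`, `label`, `probability`, `pred_label`, `confidence`,
#'   `checkpoint_epoch`, `inner_val_accuracy`), aggregate `metrics`, the
#'   config, the initialization mode and the seed.
#' @export
run_loocv <- function(data, config = classifier_config(), augment = NULL,
                      init = "random", coverage = 0.95, seed = 1L) {
  if (!is.data.frame(data) || !all(c("volume", "label") %in% names(data)))
    stop_input("`data` must be a tibble with `volume` and `label` columns")
  n <- nrow(data)
  if (n < 4L) stop_config("LOOCV needs at least 4 samples")
  if (length(unique(data$label)) < 2L)
    stop_config("dataset contains a single class")
  transfer <- inherits(init, "encoder_weights")
  if (!transfer && !identical(init, "random"))
    stop_param('`init` must be "random" or an `encoder_weights` object')
  ids <- if ("id" %in% names(data)) data$id else sprintf("vol%03d", seq_len(n))
  shp <- dim(data$volume[[1]])

  windowed <- window_volumes(data$volume, coverage)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fold_seed <- derive_seed(seed, 3L, i)
    prep <- prep_fold(windowed, setdiff(seq_len(n), i), i)
    cfg <- config
    cfg$seed <- fold_seed
    model <- build_classifier(cfg, input_shape = shp)
    if (transfer) model <- initialize_from_encoder(model, init)
    fit <- train_classifier(model,
                            tibble(volume = prep$train,
                                   label = data$label[-i]),
                            augment = augment)
    pr <- predict(fit, prep$test[[1]])
    rows[[i]] <- tibble(fold = i, id = ids[i], label = data$label[i],
                        probability = pr$probability,
                        pred_label = pr$label,
                        confidence = pr$confidence,
                        checkpoint_epoch = fit$checkpoint_epoch,
                        inner_val_accuracy = fit$best_val_accuracy)
  }
  predictions <- dplyr::bind_rows(rows)
  structure(list(predictions = predictions,
                 metrics = confusion_metrics(predictions$label,
                                             predictions$pred_label),
                 config = config,
                 init_mode = if (transfer) "transfer" else "random",
                 coverage = coverage,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' Repeated-LOOCV hyperparameter grid search
#'
#' For every configuration of the grid, repeats the complete LOOCV
#' `repeats` times (default 15) with distinct derived seeds, and reports
#' per-configuration metric ranges (min-max) and means. The best
#' configuration is the one with the highest mean accuracy; ties break
#' toward fewer trainable parameters, then the lower grid index.
#'
#' @param data Labeled dataset tibble.
#' @param grid Configuration tibble from [hyperparameter_grid()] (columns
#'   `config_id`, `n_conv_layers`, `filters`, `fc_nodes`).
#' @param repeats LOOCV repetitions per configuration.
#' @param base_config [classifier_config()] supplying the optimization
#'   settings shared by all grid points.
#' @param augment,init,coverage,seed As in [run_loocv()].
#' @return An object of class `grid_search_result` with `runs` (one row per
#'   config x repeat, `cv` list-column), `summary` (per-config min/mean/max
#'   of each metric), and `best` (one summary row).
#' @export
run_grid_search <- function(data, grid = hyperparameter_grid(), repeats = 15L,
                            base_config = classifier_config(),
                            augment = NULL, init = "random",
                            coverage = 0.95, seed = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop_input("`grid` must be a non-empty configuration tibble")
  check_scalar_number(repeats, "repeats", lower = 1)
  shp <- dim(data$volume[[1]])
  runs <- vector("list", nrow(grid) * repeats)
  r_i <- 0L
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$n_conv_layers <- grid$n_conv_layers[g]
    cfg$filters <- rep_len(as.integer(grid$filters[g]), cfg$n_conv_layers)
    cfg$fc_nodes <- as.integer(grid$fc_nodes[g])
    for (r in seq_len(repeats)) {
      cv <- run_loocv(data, cfg, augment = augment, init = init,
                      coverage = coverage, seed = derive_seed(seed, g, r))
      r_i <- r_i + 1L
      runs[[r_i]] <- tibble(config_id = grid$config_id[g],
                            n_conv_layers = grid$n_conv_layers[g],
                            filters = grid$filters[g],
                            fc_nodes = grid$fc_nodes[g],
                            rep = r,
                            accuracy = cv$metrics$accuracy,
                            sensitivity = cv$metrics$sensitivity,
                            specificity = cv$metrics$specificity,
                            cv = list(cv))
    }
  }
  runs <- dplyr::bind_rows(runs)
  rng3 <- function(x) list(min(x), mean(x), max(x))
  summary <- runs |>
    dplyr::group_by(.data$config_id, .data$n_conv_layers, .data$filters,
                    .data$fc_nodes) |>
    dplyr::summarise(dplyr::across(c("accuracy", "sensitivity", "specificity"),
                                   list(min = ~min(.x), mean = ~mean(.x),
                                        max = ~max(.x))),
                     .groups = "drop")
  n_par <- vapply(seq_len(nrow(summary)), function(i) {
    cfg <- base_config
    cfg$n_conv_layers <- summary$n_conv_layers[i]
    cfg$filters <- rep_len(as.integer(summary$filters[i]), cfg$n_conv_layers)
    cfg$fc_nodes <- as.integer(summary$fc_nodes[i])
    n_parameters(build_classifier(cfg, input_shape = shp))
  }, numeric(1))
  summary$n_parameters <- n_par
  best_ord <- order(-summary$accuracy_mean, summary$n_parameters,
                    summary$config_id)
  structure(list(runs = runs, summary = summary,
                 best = summary[best_ord[1], ],
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "grid_search_result")
}

#' Confidence-ranked triage curve
#'
#' Selective-prediction analysis: predictions are ranked from most to least
#' confident, and for each coverage fraction `c` the accuracy over the
#' `ceil(c * N)` most confident predictions is reported (ties broken by
#' sample order). At coverage 1 this reproduces the overall accuracy
#' exactly; on a calibrated model the curve rises as coverage falls,
#' quantifying how many cases could be auto-classified while deferring the
#' uncertain rest to a human reader.
#'
#' @param cv A `cv_result` from [run_loocv()].
#' @param coverages Fractions in `(0, 1]`, ordered as desired.
#' @return A tibble of class `triage_curve` with columns `coverage`, `n`,
#'   `accuracy`.
#' @export
triage_curve <- function(cv, coverages = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  stopifnot(inherits(cv, "cv_result"))
  if (any(!is.finite(coverages)) || any(coverages <= 0) || any(coverages > 1))
    stop_param("`coverages` must lie in (0, 1]")
  pr <- cv$predictions
  if (nrow(pr) < 1L) stop_input("cv result has no predictions")
  ord <- order(-pr$confidence, seq_len(nrow(pr)))
  correct <- (pr$pred_label == pr$label)[ord]
  out <- tibble(coverage = coverages,
                n = as.integer(ceiling(coverages * nrow(pr))))
  out$accuracy <- vapply(out$n, function(m) mean(correct[seq_len(m)]), numeric(1))
  class(out) <- c("triage_curve", class(out))
  out
}

#' Paired comparison of transfer versus random initialization
#'
#' Runs LOOCV once with random initialization and once with transferred
#' encoder weights for each of `n_seeds` paired seeds: both arms of a pair
#' share the same derived seed, hence identical fold order, inner splits,
#' augmentation draws and fully connected initialization — the arms differ
#' only in the convolution initialization. Reports per-seed accuracies and
#' the mean improvement in percentage points.
#'
#' @param data Labeled dataset tibble.
#' @param config A [classifier_config()] object.
#' @param augment Optional [augmentation_config()].
#' @param weights An `encoder_weights` object for the transfer arm.
#' @param n_seeds Number of paired seeds (>= 1).
#' @param coverage Window coverage fraction.
#' @param seed Integer master seed.
#' @return An object of class `init_comparison` with `per_seed` (tibble of
#'   per-seed accuracies and `improvement_pp`), `summary` (one row with
#'   mean accuracies and `mean_improvement_pp`), and the paired `cv`
#'   objects.
#' @export
compare_initializations <- function(data, config = classifier_config(),
                                    augment = NULL, weights,
                                    n_seeds = 10L, coverage = 0.95,
                                    seed = 1L) {
  stopifnot(inherits(weights, "encoder_weights"))
  check_scalar_number(n_seeds, "n_seeds", lower = 1)
  rows <- vector("list", n_seeds)
  cvs <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    seed_s <- derive_seed(seed, 7L, s)
    cv_r <- run_loocv(data, config, augment = augment, init = "random",
                      coverage = coverage, seed = seed_s)
    cv_t <- run_loocv(data, config, augment = augment, init = weights,
                      coverage = coverage, seed = seed_s)
    rows[[s]] <- tibble(seed_index = s, seed = seed_s,
                        accuracy_random = cv_r$metrics$accuracy,
                        accuracy_transfer = cv_t$metrics$accuracy,
                        improvement_pp = 100 * (cv_t$metrics$accuracy -
                                                cv_r$metrics$accuracy))
    cvs[[s]] <- list(random = cv_r, transfer = cv_t)
  }
  per_seed <- dplyr::bind_rows(rows)
  summary <- tibble(n_seeds = as.integer(n_seeds),
                    mean_accuracy_random = mean(per_seed$accuracy_random),
                    mean_accuracy_transfer = mean(per_seed$accuracy_transfer),
                    mean_improvement_pp = mean(per_seed$improvement_pp))
  structure(list(per_seed = per_seed, summary = summary, cv_pairs = cvs,
                 seed = as.integer(seed)),
            class = "init_comparison")
}

#' Run the packaged synthetic transfer benchmark
#'
#' End-to-end reproduction of the transfer-learning comparison at desk
#' scale: generates the 50-volume unlabeled source corpus of
#' [benchmark_config()], windows and normalizes it, extracts patches and
#' pretrains the autoencoder once; then, for each of the configured paired
#' seeds, generates a fresh 20-volume labeled target dataset and runs one
#' paired LOOCV comparison (random versus transfer initialization, both
#' arms sharing data, folds, splits and dense-layer initialization). Each
#' replicate thus samples a new small-data draw, which is the dominant
#' source of variability at this scale; the reported mean improvement
#' marginalizes over it.
#'
#' @param bench A [benchmark_config()] object.
#' @param seed Integer master seed for the whole benchmark.
#' @return A list of class `transfer_benchmark` with the last replicate's
#'   `data`, the trained `weights`, and the `comparison`
#'   (`init_comparison` with one row per paired seed).
#' @export
run_transfer_benchmark <- function(bench = benchmark_config(), seed = 1L) {
  stopifnot(inherits(bench, "benchmark_config"))
  params <- bench$target_params
  src_params <- params
  src_params$seed <- derive_seed(seed, 22L)
  corpus <- generate_source_corpus(bench$n_source, src_params,
                                   lesion_prevalence = bench$source_prevalence,
                                   lesion_radius_range = bench$source_radius_range)
  # source-side preprocessing mirrors the target pipeline: per-image windows,
  # then brightness normalization with corpus-level statistics, so the
  # pretrained filters see inputs on the same scale the classifier will
  corpus$volume <- window_volumes(corpus$volume, bench$coverage)
  corpus_norm <- fit_normalizer(corpus$volume)
  corpus$volume <- lapply(corpus$volume, apply_normalizer, norm = corpus_norm)
  patches <- extract_corpus_patches(corpus,
                                    patch_shape = c(25L, 25L, 4L),
                                    n_per_volume = bench$patches_per_volume,
                                    seed = derive_seed(seed, 23L))
  ae_cfg <- bench$autoencoder
  ae_cfg$seed <- derive_seed(seed, 24L)
  weights <- train_autoencoder(patches, ae_cfg)

  rows <- vector("list", bench$n_seeds)
  cvs <- vector("list", bench$n_seeds)
  data <- NULL
  for (s in seq_len(bench$n_seeds)) {
    params$seed <- derive_seed(seed, 21L, s)
    data <- generate_labeled_dataset(bench$n_healthy, bench$n_lesion, params)
    cmp_s <- compare_initializations(data, bench$classifier,
                                     augment = bench$augment,
                                     weights = weights,
                                     n_seeds = 1L,
                                     coverage = bench$coverage,
                                     seed = derive_seed(seed, 25L, s))
    row <- cmp_s$per_seed
    row$seed_index <- s
    rows[[s]] <- row
    cvs[[s]] <- cmp_s$cv_pairs[[1]]
  }
  per_seed <- dplyr::bind_rows(rows)
  comparison <- structure(
    list(per_seed = per_seed,
         summary = tibble(n_seeds = as.integer(bench$n_seeds),
                          mean_accuracy_random = mean(per_seed$accuracy_random),
                          mean_accuracy_transfer = mean(per_seed$accuracy_transfer),
                          mean_improvement_pp = mean(per_seed$improvement_pp)),
         cv_pairs = cvs,
         seed = as.integer(seed)),
    class = "init_comparison")
  structure(list(data = data, weights = weights, comparison = comparison,
                 bench = bench, seed = as.integer(seed)),
            class = "transfer_benchmark")
}
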