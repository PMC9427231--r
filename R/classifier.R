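#' Build an untrained 3D CNN classifier
#'
#' Constructs the network of the configured architecture: a stack of 3x3x3,
#' stride-1, same-padded, ReLU-activated convolutions, a flattening step,
#' one ReLU fully connected layer, and a single sigmoid output unit giving
#' the probability of class "unhealthy" (the complementary class probability
#' is its complement). Weights are drawn from a seeded random distribution.
#'
#' @param config A [classifier_config()] object.
#' @param input_shape Integer volume shape `(height, width, depth)` the
#'   classifier will consume; fixes the fully connected layer's size.
#' @return An object of class `cnn3d` (untrained model).
#' @export
build_classifier <- function(config = classifier_config(),
                             input_shape = c(64L, 64L, 16L)) {
  stopifnot(inherits(config, "classifier_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 3L))
    stop_shape(sprintf("input shape %s is below the 3x3x3 receptive field",
                       fmt_shape(input_shape)))
  params <- with_seed_local(config$seed, classifier_init_params(config, input_shape))
  structure(list(config = config, input_shape = input_shape,
                 params = params, init_mode = "random"),
            class = "cnn3d")
}

#' Number of trainable parameters of a classifier
#'
#' @param model A `cnn3d` or `cnn3d_fit` object.
#' @return Integer parameter count over all kernels, weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Initialize classifier convolutions from pretrained encoder weights
#'
#' Copies encoder layer i's kernel and bias into classifier convolution i,
#' in order, for as many layers as both networks share. On an exact shape
#' match the tensors are copied bitwise; when filter counts differ, the
#' leading sub-tensor of matching shape is copied and the remaining filters
#' keep their random initialization. Fully connected layers are untouched
#' and every layer remains trainable.
#'
#' @param model An untrained `cnn3d` from [build_classifier()].
#' @param weights An `encoder_weights` object.
#' @return The model with transferred convolution weights
#'   (`init_mode = "transfer"`).
#' @export
initialize_from_encoder <- function(model, weights) {
  stopifnot(inherits(model, "cnn3d"), inherits(weights, "encoder_weights"))
  n_copy <- min(model$config$n_conv_layers, length(weights$layers))
  for (i in seq_len(n_copy)) {
    ek <- weights$layers[[i]]$kernel
    eb <- weights$layers[[i]]$bias
    if (any(dim(ek)[1:3] != c(3L, 3L, 3L)))
      stop_shape(sprintf(
        "encoder layer %d has kernel spatial shape %s; classifier convolutions are 3x3x3",
        i, fmt_shape(dim(ek)[1:3])))
    nm <- sprintf("conv%d.W", i)
    ck <- model$params[[nm]]
    ci <- min(dim(ek)[4], dim(ck)[4])
    co <- min(dim(ek)[5], dim(ck)[5])
    ck[, , , seq_len(ci), seq_len(co)] <- ek[, , , seq_len(ci), seq_len(co)]
    model$params[[nm]] <- ck
    cb <- model$params[[sprintf("conv%d.b", i)]]
    cb[seq_len(co)] <- eb[seq_len(co)]
    model$params[[sprintf("conv%d.b", i)]] <- cb
  }
  model$init_mode <- "transfer"
  model
}

#' Train the 3D CNN classifier
#'
#' Minimizes binary cross-entropy with Adam. A stratified
#' `validation_fraction` of the training samples is held out before any
#' augmentation; augmented copies are generated for the inner-training
#' portion only. After every epoch the inner-validation accuracy is
#' measured, and the weights of the epoch with the highest validation
#' accuracy (ties broken toward the earliest epoch) are checkpointed and
#' returned.
#'
#' @param model An untrained `cnn3d` (optionally transfer-initialized).
#' @param data Tibble with `volume` (list-column of preprocessed arrays of
#'   the model's input shape) and `label` (0/1); both classes must survive
#'   the inner split.
#' @param augment Optional [augmentation_config()] applied to the
#'   inner-training samples (per-sample seeds derived from the model seed).
#' @return An object of class `cnn3d_fit`: checkpointed parameters, the
#'   training history (per-epoch train loss and validation accuracy), the
#'   checkpoint epoch, and the initialization mode.
#' @export
train_classifier <- function(model, data, augment = NULL) {
  stopifnot(inherits(model, "cnn3d"))
  if (!is.data.frame(data) || !all(c("volume", "label") %in% names(data)))
    stop_input("`data` must be a tibble with `volume` and `label` columns")
  if (nrow(data) < 2L) stop_config("need at least 2 training samples")
  if (length(unique(data$label)) < 2L)
    stop_config("training data contain a single class; metrics are undefined")
  if (!is.null(augment)) stopifnot(inherits(augment, "augmentation_config"))
  config <- model$config
  shp <- model$input_shape
  for (v in data$volume)
    if (!all(dim(v) == shp))
      stop_shape(sprintf("training volume of shape %s does not match model input %s",
                         fmt_shape(dim(v)), fmt_shape(shp)))

  with_seed_local(derive_seed(config$seed, 11L), {
    # stratified inner validation split (before augmentation)
    val_idx <- unlist(lapply(split(seq_len(nrow(data)), data$label), function(ix) {
      nv <- max(1L, round(config$validation_fraction * length(ix)))
      if (nv >= length(ix)) nv <- length(ix) - 1L
      if (nv <= 0L) return(integer())
      sample(ix, nv)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(nrow(data)), val_idx)
    if (length(unique(data$label[train_idx])) < 2L)
      stop_config("inner-training split lost a class; provide more samples")

    train_vols <- data$volume[train_idx]
    train_labs <- data$label[train_idx]
    if (!is.null(augment) && augment$k > 0L) {
      for (j in seq_along(train_idx)) {
        cfg_j <- augment
        cfg_j$seed <- derive_seed(config$seed, 13L, j, augment$seed)
        aug <- augment_sample(train_vols[[j]], train_labs[j], cfg_j)
        train_vols <- c(train_vols, aug$volume)
        train_labs <- c(train_labs, aug$label)
      }
    }
    val_vols <- data$volume[val_idx]
    val_labs <- data$label[val_idx]

    params <- model$params
    state <- adam_init(params)
    lr_mult <- lr_multipliers(params)
    running_center <- NULL
    t_step <- 0
    n_tr <- length(train_vols)
    history <- tibble(epoch = seq_len(config$epochs),
                      train_loss = NA_real_, val_accuracy = NA_real_)
    best <- list(acc = -Inf, epoch = NA_integer_, params = params)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        fw <- classifier_forward(params, config, shp, train_vols[b],
                                 keep_cache = TRUE,
                                 center = running_center, batch_center = TRUE)
        if (!is.null(fw$batch_mean)) {
          running_center <- if (is.null(running_center)) fw$batch_mean
                            else 0.9 * running_center + 0.1 * fw$batch_mean
        }
        grads <- classifier_backward(params, config, shp, fw$cache,
                                     train_labs[b])
        ep_loss <- ep_loss + sum(bce_loss(fw$p, train_labs[b]))
        grads <- lapply(grads, `/`, length(b))
        t_step <- t_step + 1
        upd <- adam_step(params, grads, state, config$learning_rate, t_step,
                         mult = lr_mult)
        params <- upd$params; state <- upd$state
      }
      val_p <- if (length(val_vols))
        classifier_forward(params, config, shp, val_vols,
                           center = running_center)$p else numeric()
      val_acc <- if (length(val_labs)) mean(as.integer(val_p >= 0.5) == val_labs)
                 else NA_real_
      history$train_loss[epoch] <- ep_loss / n_tr
      history$val_accuracy[epoch] <- val_acc
      if (!is.na(val_acc) && val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, params = params,
                     center = running_center)
      }
    }
    if (!is.finite(best$acc)) best <- list(acc = NA_real_, epoch = config$epochs,
                                           params = params,
                                           center = running_center)
  })
  structure(list(params = best$params,
                 center = best$center,
                 final_params = params,
                 config = config, input_shape = shp,
                 history = history,
                 checkpoint_epoch = best$epoch,
                 best_val_accuracy = best$acc,
                 init_mode = model$init_mode),
            class = "cnn3d_fit")
}

#' Predict with a trained classifier
#'
#' Returns the sigmoid probability of class "unhealthy", the hard label
#' under the 0.5 threshold (ties at exactly 0.5 map to class 1), and the
#' confidence score: the disparity `|p - (1 - p)| = |2p - 1|` between the
#' two class probabilities, which grows as the model becomes more certain.
#'
#' @param object A `cnn3d_fit`.
#' @param newdata A 3D array of the training shape, or a tibble with a
#'   `volume` list-column.
#' @param ... Unused.
#' @return A tibble with columns `probability`, `label`, `confidence`
#'   (one row per input volume).
#' @export
predict.cnn3d_fit <- function(object, newdata, ...) {
  vols <- if (is.array(newdata) && length(dim(newdata)) == 3L) list(newdata)
          else as_volume_list(newdata, "newdata")
  shp <- object$input_shape
  for (v in vols)
    if (!all(dim(v) == shp))
      stop_shape(sprintf("volume of shape %s does not match model input %s",
                         fmt_shape(dim(v)), fmt_shape(shp)))
  chunks <- split(seq_along(vols), ceiling(seq_along(vols) / 16))
  p <- unlist(lapply(chunks, function(ix)
    classifier_forward(object$params, object$config, shp, vols[ix],
                       center = object$center)$p),
    use.names = FALSE)
  tibble(probability = p,
         label = as.integer(p >= 0.5),
         confidence = abs(2 * p - 1))
}
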