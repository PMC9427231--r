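#' Tidy per-fold predictions of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold prediction tibble.
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble: confusion counts, accuracy, sensitivity,
#'   specificity, plus the initialization mode, the mean inner-validation
#'   accuracy across folds (labeled separately from the held-out LOOCV
#'   accuracy), and the seed.
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::mutate(x$metrics,
                init_mode = x$init_mode,
                mean_inner_val_accuracy = mean(x$predictions$inner_val_accuracy),
                n_folds = nrow(x$predictions),
                seed = x$seed)
}

#' Tidy grid-search runs
#'
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @return One row per configuration x repeat (without the nested cv
#'   objects).
#' @export
tidy.grid_search_result <- function(x, ...) dplyr::select(x$runs, -"cv")

#' Per-configuration grid-search summary
#'
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @return The per-configuration min/mean/max metric table with parameter
#'   counts.
#' @export
glance.grid_search_result <- function(x, ...) x$summary

#' Tidy per-seed rows of an initialization comparison
#'
#' @param x An `init_comparison`.
#' @param ... Unused.
#' @return The per-seed accuracy tibble.
#' @export
tidy.init_comparison <- function(x, ...) x$per_seed

#' One-row summary of an initialization comparison
#'
#' @param x An `init_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with mean accuracies per arm and the mean
#'   improvement in percentage points.
#' @export
glance.init_comparison <- function(x, ...) x$summary

#' Training history of a fitted classifier
#'
#' @param x A `cnn3d_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.cnn3d_fit <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `cnn3d_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the checkpoint epoch, its validation
#'   accuracy, the parameter count and the initialization mode.
#' @export
glance.cnn3d_fit <- function(x, ...) {
  tibble(checkpoint_epoch = x$checkpoint_epoch,
         best_val_accuracy = x$best_val_accuracy,
         n_parameters = n_parameters(x),
         init_mode = x$init_mode,
         epochs = x$config$epochs)
}

#' Plot a triage curve
#'
#' Accuracy among the most confident fraction of predictions, against the
#' fraction retained.
#'
#' @param object A `triage_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$coverage, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "coverage (fraction of most confident predictions)",
                  y = "accuracy", title = "Confidence-ranked triage curve")
}

#' Plot classifier training history
#'
#' @param object A `cnn3d_fit`.
#' @param ... Unused.
#' @return A ggplot object with training loss and validation accuracy
#'   panels; the checkpointed epoch is marked.
#' @export
autoplot.cnn3d_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_accuracy"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$checkpoint_epoch, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Plot per-seed accuracies of an initialization comparison
#'
#' @param object An `init_comparison`.
#' @param ... Unused.
#' @return A ggplot object with paired per-seed accuracies for the random
#'   and transfer arms.
#' @export
autoplot.init_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_seed,
                           c("accuracy_random", "accuracy_transfer"),
                           names_to = "arm", values_to = "accuracy",
                           names_prefix = "accuracy_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$accuracy,
                                  group = .data$seed_index)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "LOOCV accuracy",
                  title = "Transfer vs random initialization (paired seeds)")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> LOOCV, %d folds, init = %s, seed = %d\n",
              nrow(x$predictions), x$init_mode, x$seed))
  print(x$metrics)
  invisible(x)
}

#' @export
print.init_comparison <- function(x, ...) {
  cat(sprintf("<init_comparison> %d paired seeds\n", nrow(x$per_seed)))
  print(x$summary)
  invisible(x)
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d configurations x %d repeats\n",
              nrow(x$summary), x$repeats))
  print(x$summary)
  cat("best configuration:\n")
  print(x$best)
  invisible(x)
}

#' @export
print.encoder_weights <- function(x, ...) {
  filt <- vapply(x$layers, function(l) dim(l$kernel)[5], numeric(1))
  cat(sprintf("<encoder_weights> %d conv layer(s) [%s], patch %s, final MSE %s\n",
              length(x$layers), paste(filt, collapse = ", "),
              fmt_shape(x$patch_shape),
              if (is.na(x$final_loss)) "NA (untrained)"
              else format(x$final_loss, digits = 4)))
  invisible(x)
}

#' @export
print.cnn3d_fit <- function(x, ...) {
  cat(sprintf("<cnn3d_fit> %d conv layer(s), %d fc nodes, %s init; checkpoint epoch %d (val acc %s)\n",
              x$config$n_conv_layers, x$config$fc_nodes, x$init_mode,
              x$checkpoint_epoch, format(x$best_val_accuracy, digits = 3)))
  invisible(x)
}
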