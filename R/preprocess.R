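#' Stack 2D slices into a 3D volume
#'
#' @param slices List of 2D numeric matrices, all of the same height and
#'   width, ordered by depth.
#' @return A 3D array of shape `(height, width, n_slices)`; slice `k`
#'   occupies depth index `k`.
#' @export
stack_slices <- function(slices) {
  if (!is.list(slices) || length(slices) == 0L)
    stop_input("`slices` must be a non-empty list of 2D matrices")
  d0 <- dim(slices[[1]])
  if (is.null(d0) || length(d0) != 2L)
    stop_shape("slice 1 is not a 2D matrix")
  for (k in seq_along(slices)) {
    dk <- dim(slices[[k]])
    if (is.null(dk) || length(dk) != 2L || any(dk != d0))
      stop_shape(sprintf("slice %d has shape %s, expected %s",
                         k, fmt_shape(if (is.null(dk)) length(slices[[k]]) else dk),
                         fmt_shape(d0)))
  }
  array(unlist(slices, use.names = FALSE), dim = c(d0, length(slices)))
}

#' Compute an intensity window covering a fraction of voxel intensities
#'
#' Finds the symmetric central window `[lower, upper]` whose endpoints are
#' the order statistics bracketing the `(1 - coverage)/2` and
#' `1 - (1 - coverage)/2` quantiles, rounded outward so that the realized
#' fraction of in-window voxels is always at least `coverage`.
#'
#' @param volume 3D array of intensities.
#' @param coverage Target fraction of voxels inside the window, in `(0, 1]`;
#'   the default 0.95 keeps the central 95% of the intensity distribution.
#' @return An object of class `window_params` with fields `lower`, `upper`,
#'   `coverage` and `realized_coverage`.
#' @export
compute_window <- function(volume, coverage = 0.95) {
  check_volume(volume)
  if (length(volume) == 0L) stop_input("`volume` is empty")
  check_scalar_number(coverage, "coverage", 1e-12, 1)
  v <- sort(as.vector(volume))
  n <- length(v)
  p_lo <- (1 - coverage) / 2
  idx_lo <- max(1L, min(n, floor(1 + (n - 1) * p_lo)))
  idx_hi <- max(1L, min(n, ceiling(1 + (n - 1) * (1 - p_lo))))
  lower <- v[idx_lo]; upper <- v[idx_hi]
  structure(list(lower = lower, upper = upper, coverage = coverage,
                 realized_coverage = mean(volume >= lower & volume <= upper)),
            class = "window_params")
}

#' Clip and rescale a volume into its intensity window
#'
#' Intensities are clipped to `[lower, upper]` and rescaled linearly to
#' `[0, 1]`. A degenerate window (`lower == upper`) maps everything to 0.
#'
#' @param volume 3D array of intensities.
#' @param window A `window_params` object from [compute_window()].
#' @return A 3D array in `[0, 1]` of the same shape.
#' @export
apply_window <- function(volume, window) {
  check_volume(volume)
  stopifnot(inherits(window, "window_params"))
  lo <- window$lower; hi <- window$upper
  if (hi <= lo) return(array(0, dim = dim(volume)))
  out <- (pmin(pmax(volume, lo), hi) - lo) / (hi - lo)
  array(out, dim = dim(volume))
}

#' Fit brightness-normalization statistics on training volumes
#'
#' Pools all voxels of the training volumes (and only the training volumes,
#' so held-out data never leak into the statistics) and records their mean,
#' minimum and maximum. Volumes are expected to be windowed already.
#'
#' @param training_volumes List of 3D arrays, or a dataset tibble with a
#'   `volume` list-column.
#' @return An object of class `normalizer_params` with fields `train_mean`,
#'   `train_min`, `train_max`.
#' @export
fit_normalizer <- function(training_volumes) {
  vols <- as_volume_list(training_volumes, "training_volumes")
  total <- 0; count <- 0; mn <- Inf; mx <- -Inf
  for (v in vols) {
    check_volume(v)
    total <- total + sum(v); count <- count + length(v)
    mn <- min(mn, min(v)); mx <- max(mx, max(v))
  }
  if (count == 0L) stop_input("training volumes are empty")
  structure(list(train_mean = total / count, train_min = mn, train_max = mx),
            class = "normalizer_params")
}

#' Normalize a volume with training-set statistics
#'
#' Applies `(v - train_mean) / (train_max - train_min)` identically to
#' training and held-out volumes. A degenerate range maps everything to 0.
#'
#' @param volume 3D array of intensities.
#' @param norm A `normalizer_params` object from [fit_normalizer()].
#' @return A 3D array of the same shape, centered on the training mean.
#' @export
apply_normalizer <- function(volume, norm) {
  check_volume(volume)
  stopifnot(inherits(norm, "normalizer_params"))
  rng <- norm$train_max - norm$train_min
  if (rng <= 0) return(array(0, dim = dim(volume)))
  array((volume - norm$train_mean) / rng, dim = dim(volume))
}

# Window every volume with its own per-image window. Used by the harness;
# per-image windows involve no cross-sample statistics, so they can be
# computed once for all folds without leakage.
window_volumes <- function(volumes, coverage = 0.95) {
  lapply(as_volume_list(volumes), function(v) apply_window(v, compute_window(v, coverage)))
}

#' Serialize normalizer parameters as JSON
#'
#' @param norm A `normalizer_params` object.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_normalizer <- function(norm, path) {
  stopifnot(inherits(norm, "normalizer_params"))
  jsonlite::write_json(unclass(norm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read normalizer parameters from JSON
#'
#' @param path A `.json` file written by [write_normalizer()].
#' @return A `normalizer_params` object.
#' @export
read_normalizer <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("train_mean", "train_min", "train_max") %in% names(x)))
    stop_format(sprintf("%s is not a normalizer file", path))
  structure(x[c("train_mean", "train_min", "train_max")],
            class = "normalizer_params")
}
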