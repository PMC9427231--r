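#' Phantom generator parameters
#'
#' Parameters for the synthetic "brain phantom" generator: an ellipsoidal
#' tissue region on a dark background, optionally carrying one spherical
#' high-intensity lesion, degraded by Rician magnitude noise (the noise model
#' of MR magnitude images).
#'
#' @param shape Integer vector of voxel counts `(height, width, depth)`.
#'   Each axis must be at least `c(8, 8, 4)`; volumes intended for
#'   patch-based autoencoder pretraining need at least `c(25, 25, 4)`
#'   (enforced by [extract_patches()]).
#' @param background_level Background intensity in `[0, 1]`.
#' @param tissue_level Intensity of the ellipsoidal tissue region, in
#'   `(background_level, 1]`.
#' @param lesion_radius_range Length-2 numeric `(min, max)` lesion radius in
#'   voxels; the radius of a lesion is drawn uniformly from this range.
#' @param lesion_contrast Additive intensity of the lesion over
#'   `tissue_level`; must be positive.
#' @param lesion_center_fraction Lesion centers are drawn from the tissue
#'   ellipsoid shrunk by this factor (in `(0, 1]`), so lesions sit in the
#'   core of the tissue rather than grazing its boundary; at desk scale
#'   this keeps held-out lesion positions within the rigid-augmentation
#'   orbit of a small training set.
#' @param edema_fraction Peak intensity of the peritumoral edema halo as a
#'   fraction of `lesion_contrast`. The halo extends to twice the core
#'   radius, confined to tissue, decaying linearly to zero; `0` disables
#'   it. Edema makes the effective lesion footprint several times the core
#'   volume, as in T2-weighted tumor imaging.
#' @param noise_sigma Standard deviation of each Gaussian channel of the
#'   Rician noise, in intensity units; `0` disables noise.
#' @param seed Integer master seed for dataset-level generators.
#'
#' @return An object of class `phantom_params`.
#' @seealso [make_phantom()], [generate_labeled_dataset()],
#'   [generate_source_corpus()]
#' @export
phantom_params <- function(shape = c(64L, 64L, 16L),
                           background_level = 0.05,
                           tissue_level = 0.5,
                           lesion_radius_range = c(3, 5),
                           lesion_contrast = 0.25,
                           lesion_center_fraction = 0.5,
                           edema_fraction = 0.4,
                           noise_sigma = 0.05,
                           seed = 1L) {
  if (length(shape) != 3L || any(shape != round(shape)))
    stop_param("`shape` must be three integer voxel counts (height, width, depth)")
  shape <- as.integer(shape)
  if (any(shape < c(8L, 8L, 4L)))
    stop_param(sprintf("`shape` %s is below the minimum (8, 8, 4)", fmt_shape(shape)))
  check_scalar_number(background_level, "background_level", 0, 1)
  check_scalar_number(tissue_level, "tissue_level", 0, 1)
  if (background_level >= tissue_level)
    stop_param("`background_level` must be strictly below `tissue_level`")
  if (length(lesion_radius_range) != 2L || any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop_param("`lesion_radius_range` must be positive (min, max) voxels")
  check_scalar_number(lesion_contrast, "lesion_contrast", lower = 1e-12)
  if (tissue_level + lesion_contrast > 1 + 1e-12)
    stop_param("`tissue_level` + `lesion_contrast` must not exceed 1")
  check_scalar_number(lesion_center_fraction, "lesion_center_fraction", 1e-6, 1)
  check_scalar_number(edema_fraction, "edema_fraction", 0, 1)
  check_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  structure(list(shape = shape,
                 background_level = background_level,
                 tissue_level = tissue_level,
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = lesion_contrast,
                 lesion_center_fraction = lesion_center_fraction,
                 edema_fraction = edema_fraction,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Rigid augmentation configuration
#'
#' Controls the label-preserving rigid perturbations used to expand a small
#' training set: each augmented copy is produced by one composed affine
#' (in-plane rotation about the slice center into recomputed bounds, then
#' translation).
#'
#' @param k Number of random rigid operations generated per input volume.
#' @param max_angle Maximum absolute rotation angle in degrees; angles are
#'   drawn uniformly from `[-max_angle, max_angle]`.
#' @param max_shift_fraction Maximum translation along each in-plane axis,
#'   as a fraction of that axis' extent; must lie in `[0, 0.5)`.
#' @param fill_value Intensity assigned to voxels exposed by the transform
#'   (background after windowing, hence default `0`).
#' @param interpolation `"bilinear"` (intensity images) or `"nearest"`.
#' @param seed Integer seed; identical `(sample, config)` pairs reproduce
#'   identical augmented sets.
#'
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(k = 14L,
                                max_angle = 25,
                                max_shift_fraction = 0.1,
                                fill_value = 0,
                                interpolation = c("bilinear", "nearest"),
                                seed = 1L) {
  check_scalar_number(k, "k", lower = 0)
  if (k != round(k)) stop_param("`k` must be a whole number")
  check_scalar_number(max_angle, "max_angle", lower = 0)
  check_scalar_number(max_shift_fraction, "max_shift_fraction", 0, 0.5 - 1e-12)
  check_scalar_number(fill_value, "fill_value")
  structure(list(k = as.integer(k), max_angle = max_angle,
                 max_shift_fraction = max_shift_fraction,
                 fill_value = fill_value,
                 interpolation = match.arg(interpolation),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Autoencoder configuration
#'
#' Architecture and optimization settings for the patch-based 3D
#' convolutional autoencoder whose encoder weights seed the classifier.
#' The encoder is a stack of 3x3x3, stride-1, same-padded convolutions with
#' ReLU activations; the decoder mirrors it with a linear final layer, and
#' training minimizes mean squared reconstruction error with Adam.
#'
#' @param encoder_filters Ordered filter counts of the encoder convolutions
#'   (1 to 3 layers, each filter count one of 16, 32, 64).
#' @param epochs,batch_size,learning_rate Adam optimization settings.
#' @param seed Integer seed for weight initialization and batch order.
#'
#' @return An object of class `autoencoder_config`.
#' @export
autoencoder_config <- function(encoder_filters = c(16L, 32L, 64L),
                               epochs = 20L,
                               batch_size = 128L,
                               learning_rate = 1e-3,
                               seed = 1L) {
  if (length(encoder_filters) < 1L || length(encoder_filters) > 3L)
    stop_param("`encoder_filters` must list 1 to 3 encoder layers")
  if (!all(encoder_filters %in% c(16L, 32L, 64L)))
    stop_param("each encoder filter count must be one of 16, 32, 64")
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  structure(list(encoder_filters = as.integer(encoder_filters),
                 kernel = c(3L, 3L, 3L),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

#' Classifier configuration
#'
#' Architecture and optimization settings for the small 3D CNN classifier:
#' a stack of 3x3x3, stride-1, same-padded, ReLU-activated convolutions,
#' a flattening step, one ReLU fully connected layer, and a single sigmoid
#' output unit trained with binary cross-entropy. The architecture triple
#' `(n_conv_layers, filters, fc_nodes)` is drawn from the hyperparameter
#' grid of [hyperparameter_grid()].
#'
#' @param n_conv_layers Number of convolutional layers (1 to 3).
#' @param filters Filter count per convolutional layer: either a single
#'   value from 16/32/64 replicated across layers, or one value per layer.
#' @param fc_nodes Width of the fully connected layer (16, 32, or 64).
#' @param epochs,batch_size,learning_rate Adam optimization settings.
#' @param validation_fraction Fraction of the training data held out (by a
#'   stratified split) for epoch checkpointing, in `(0, 0.5]`.
#' @param seed Integer seed controlling initialization, the inner split,
#'   augmentation draws and batch order.
#'
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_conv_layers = 2L,
                              filters = 32L,
                              fc_nodes = 16L,
                              epochs = 30L,
                              batch_size = 8L,
                              learning_rate = 1e-3,
                              validation_fraction = 0.2,
                              seed = 1L) {
  check_scalar_number(n_conv_layers, "n_conv_layers", 1, 3)
  n_conv_layers <- as.integer(n_conv_layers)
  if (!length(filters) %in% c(1L, n_conv_layers))
    stop_param("`filters` must be a scalar or one value per conv layer")
  if (!all(filters %in% c(16L, 32L, 64L)))
    stop_param("each filter count must be one of 16, 32, 64")
  filters <- rep_len(as.integer(filters), n_conv_layers)
  if (!fc_nodes %in% c(16L, 32L, 64L))
    stop_param("`fc_nodes` must be one of 16, 32, 64")
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar_number(validation_fraction, "validation_fraction", 1e-6, 0.5)
  structure(list(n_conv_layers = n_conv_layers,
                 filters = filters,
                 fc_nodes = as.integer(fc_nodes),
                 kernel = c(3L, 3L, 3L), stride = 1L,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Hyperparameter grid for the classifier
#'
#' The default grid pairs each layer count with one filter count
#' (1 layer/16 filters, 2/32, 3/64) and crosses it with fully connected
#' widths 16/32/64, giving 9 configurations. `full = TRUE` expands to the
#' complete 27-configuration product of layers x filters x fc widths.
#'
#' @param full Expand to the full 3 x 3 x 3 product grid.
#' @return A tibble with columns `config_id`, `n_conv_layers`, `filters`,
#'   `fc_nodes`.
#' @export
hyperparameter_grid <- function(full = FALSE) {
  if (full) {
    g <- tidyr::expand_grid(n_conv_layers = 1:3,
                            filters = c(16L, 32L, 64L),
                            fc_nodes = c(16L, 32L, 64L))
  } else {
    g <- tidyr::expand_grid(row = 1:3, fc_nodes = c(16L, 32L, 64L))
    g <- dplyr::mutate(g,
                       n_conv_layers = .data$row,
                       filters = c(16L, 32L, 64L)[.data$row])
    g <- dplyr::select(g, "n_conv_layers", "filters", "fc_nodes")
  }
  dplyr::mutate(g, config_id = dplyr::row_number(), .before = 1)
}

#' Shipped small-data transfer benchmark configuration
#'
#' The packaged synthetic benchmark used to measure the accuracy benefit of
#' autoencoder transfer initialization over random initialization: 20
#' labeled target volumes (10 lesion-free, 10 lesion-bearing) and a
#' 50-volume unlabeled source corpus drawn from the same noise model but a
#' shifted anatomy distribution (wider lesion radius range, 50% lesion
#' prevalence). Volumes are 28 x 28 x 10 voxels and epochs are reduced so
#' that the 400 classifier fits of the paired comparison stay tractable on
#' one CPU — which is also the data- and compute-starved regime where
#' initialization matters most; augmentation is disabled here for the same
#' reason.
#'
#' @return A list of class `benchmark_config` with components
#'   `target_params`, `source_radius_range`, `source_prevalence`,
#'   `n_healthy`, `n_lesion`, `n_source`, `patches_per_volume`,
#'   `autoencoder`, `classifier`, `augment`, `coverage`, `n_seeds`.
#' @seealso [run_transfer_benchmark()]
#' @export
benchmark_config <- function() {
  structure(list(
    target_params = phantom_params(shape = c(26L, 26L, 8L),
                                   background_level = 0.05,
                                   tissue_level = 0.5,
                                   lesion_radius_range = c(1.8, 2.6),
                                   lesion_contrast = 0.35,
                                   noise_sigma = 0.06),
    source_radius_range = c(1.4, 2.6),
    source_prevalence = 0.5,
    n_healthy = 10L,
    n_lesion = 10L,
    n_source = 50L,
    patches_per_volume = 60L,
    autoencoder = autoencoder_config(encoder_filters = 16L, epochs = 8L,
                                     batch_size = 64L, learning_rate = 1e-3),
    classifier = classifier_config(n_conv_layers = 1L, filters = 16L,
                                   fc_nodes = 16L, epochs = 8L,
                                   batch_size = 8L, learning_rate = 1e-3),
    augment = NULL,
    coverage = 0.95,
    n_seeds = 10L
  ), class = "benchmark_config")
}
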