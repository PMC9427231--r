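#' Read a 3D volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return A plain 3D array of intensities, axes `(height, width, depth)`
#'   mapped from the NIfTI i/j/k voxel axes.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_io(sprintf("cannot read %s: %s",
                                                      path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L)
    stop_shape(sprintf("%s holds a rank-%d image; expected a 3D volume",
                       path, length(d)))
  array(as.numeric(img), dim = d)
}

#' Write a 3D volume as NIfTI
#'
#' Writes a valid NIfTI file with an identity affine and float32
#' intensities. `.nii` and `.nii.gz` destinations decode identically.
#'
#' @param volume 3D array.
#' @param path Destination path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  check_volume(volume)
  img <- RNifti::asNifti(volume, datatype = "float")
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop_io(sprintf("cannot write volume to %s", path))
  invisible(path)
}

WEIGHTS_FORMAT_VERSION <- 1L

#' Save network weights to disk
#'
#' Serializes an `encoder_weights` or `cnn3d_fit` object into a stable
#' container (R serialization format 3, uncompressed) with an explicit
#' format-version field checked on load. Round trips are bit-exact, and
#' `save -> load -> save` produces a byte-identical file.
#'
#' @param weights An `encoder_weights` or `cnn3d_fit` object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_weights <- function(weights, path) {
  if (!inherits(weights, "encoder_weights") && !inherits(weights, "cnn3d_fit"))
    stop_input("`weights` must be an `encoder_weights` or `cnn3d_fit` object")
  payload <- list(format = "phantomnet-weights",
                  version = WEIGHTS_FORMAT_VERSION,
                  object = weights)
  ok <- tryCatch({saveRDS(payload, path, version = 3, compress = FALSE); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write weights to %s", path))
  invisible(path)
}

#' Load network weights from disk
#'
#' @param path Path written by [save_weights()].
#' @return The stored `encoder_weights` or `cnn3d_fit` object.
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_io(sprintf("cannot read %s: %s",
                                                          path, conditionMessage(e))))
  if (!is.list(payload) || !identical(payload$format, "phantomnet-weights"))
    stop_format(sprintf("%s is not a phantomnet weights container", path))
  if (!identical(payload$version, WEIGHTS_FORMAT_VERSION))
    stop_format(sprintf("weights container version mismatch: expected %d, found %s",
                        WEIGHTS_FORMAT_VERSION, format(payload$version)))
  payload$object
}

#' Write a dataset to disk
#'
#' Writes every volume of a labeled dataset as NIfTI plus a CSV manifest
#' with columns `path`, `label`, `seed`.
#'
#' @param data Dataset tibble from [generate_labeled_dataset()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(data, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(data$id, ".nii.gz"))
  for (i in seq_len(nrow(data))) write_volume(data$volume[[i]], paths[i])
  manifest <- data.frame(path = paths,
                         label = if ("label" %in% names(data)) data$label else NA,
                         seed = seed)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
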