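#' Boundary dimensions of a rotated slice
#'
#' When a `height x width` slice is rotated by `angle` degrees, the smallest
#' axis-aligned bounds containing the rotated footprint follow from the
#' absolute sine and cosine of the rotation matrix:
#' `new_height = ceil(h|cos| + w|sin|)`, `new_width = ceil(h|sin| + w|cos|)`.
#'
#' @param height,width Slice dimensions in voxels (>= 1).
#' @param angle Rotation angle in degrees.
#' @return Named integer vector `c(height = ..., width = ...)`.
#' @export
rotated_bounds <- function(height, width, angle) {
  check_scalar_number(height, "height", lower = 1)
  check_scalar_number(width, "width", lower = 1)
  check_scalar_number(angle, "angle")
  ca <- abs(cospi(angle / 180)); sa <- abs(sinpi(angle / 180))
  c(height = as.integer(ceiling(height * ca + width * sa)),
    width = as.integer(ceiling(height * sa + width * ca)))
}

#' Create a rigid transform record
#'
#' @param angle In-plane rotation in degrees about the slice center.
#' @param shift Length-2 numeric `(dy, dx)` translation in voxels.
#' @param fill_value Intensity for voxels exposed by the transform.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle = 0, shift = c(0, 0), fill_value = 0,
                            interpolation = c("bilinear", "nearest")) {
  check_scalar_number(angle, "angle")
  if (length(shift) != 2L || !all(is.finite(shift)))
    stop_param("`shift` must be finite (dy, dx)")
  check_scalar_number(fill_value, "fill_value")
  structure(list(angle = angle, shift = as.numeric(shift),
                 fill_value = fill_value,
                 interpolation = match.arg(interpolation)),
            class = "rigid_transform")
}

#' Apply one composed rigid transform to a volume
#'
#' Every depth slice is rotated by the same angle about its center into the
#' enlarged bounds given by [rotated_bounds()], then translated by
#' `(dy, dx)` — composed as a single affine, so each voxel is interpolated
#' exactly once. Voxels with no source are set to `fill_value`.
#'
#' @param volume 3D array `(height, width, depth)`.
#' @param transform A [rigid_transform()] object.
#' @return A 3D array of shape `(new_height, new_width, depth)`.
#' @export
apply_rigid_transform <- function(volume, transform) {
  check_volume(volume)
  stopifnot(inherits(transform, "rigid_transform"))
  d <- dim(volume)
  nb <- rotated_bounds(d[1], d[2], transform$angle)
  warp_slices(volume, as.integer(d), nb[["height"]], nb[["width"]],
              transform$angle, transform$shift[1], transform$shift[2],
              transform$fill_value, transform$interpolation == "nearest")
}

#' Center-crop or pad a volume to a target shape
#'
#' Used to bring augmented volumes (whose in-plane bounds grew with the
#' rotation) back to a common training shape so they stack into tensors.
#'
#' @param volume 3D array.
#' @param shape Target integer shape `(height, width, depth)`.
#' @param fill Intensity for padded voxels.
#' @return A 3D array of shape `shape`.
#' @export
crop_pad_volume <- function(volume, shape, fill = 0) {
  check_volume(volume)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_param("`shape` must be three positive integers")
  out <- array(fill, dim = shape)
  d <- dim(volume)
  # centered overlap between source and target extents per axis
  src_lo <- integer(3); src_hi <- integer(3); dst_lo <- integer(3)
  for (a in 1:3) {
    off <- floor((d[a] - shape[a]) / 2)  # >0 crop, <0 pad
    n <- min(d[a], shape[a])
    src_lo[a] <- max(1L, off + 1L)
    dst_lo[a] <- max(1L, -off + 1L)
    src_hi[a] <- src_lo[a] + n - 1L
  }
  out[dst_lo[1]:(dst_lo[1] + (src_hi[1] - src_lo[1])),
      dst_lo[2]:(dst_lo[2] + (src_hi[2] - src_lo[2])),
      dst_lo[3]:(dst_lo[3] + (src_hi[3] - src_lo[3]))] <-
    volume[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Expand one labeled volume with random rigid operations
#'
#' Draws `k` independent rigid transforms (angle uniform on
#' `[-max_angle, max_angle]`; shifts uniform within `max_shift_fraction` of
#' each in-plane dimension), applies each to the volume, and center-crops or
#' pads the result back to the input shape. Every output carries the input's
#' label: rigid perturbations do not change the categorization of a volume.
#'
#' @param volume 3D array.
#' @param label Binary label (0/1) carried to every augmented copy.
#' @param config An [augmentation_config()] object; `config$seed` makes the
#'   draw reproducible.
#' @return A tibble with `k` rows and columns `angle`, `dy`, `dx`, `label`,
#'   `volume` (list-column of arrays shaped like the input).
#' @export
augment_sample <- function(volume, label, config = augmentation_config()) {
  check_volume(volume)
  stopifnot(inherits(config, "augmentation_config"))
  if (!label %in% c(0L, 1L)) stop_param("`label` must be 0 or 1")
  d <- dim(volume)
  k <- config$k
  if (k == 0L)
    return(tibble(angle = numeric(), dy = numeric(), dx = numeric(),
                  label = integer(), volume = list()))
  with_seed_local(config$seed, {
    angles <- runif(k, -config$max_angle, config$max_angle)
    dys <- runif(k, -config$max_shift_fraction * d[1], config$max_shift_fraction * d[1])
    dxs <- runif(k, -config$max_shift_fraction * d[2], config$max_shift_fraction * d[2])
  })
  vols <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- rigid_transform(angles[i], c(dys[i], dxs[i]),
                          fill_value = config$fill_value,
                          interpolation = config$interpolation)
    vols[[i]] <- crop_pad_volume(apply_rigid_transform(volume, tr), d,
                                 fill = config$fill_value)
  }
  tibble(angle = angles, dy = dys, dx = dxs,
         label = rep(as.integer(label), k), volume = vols)
}
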