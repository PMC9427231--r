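#' Construct one noiseless phantom volume
#'
#' Builds an ellipsoidal "head" of uniform tissue intensity on a dark
#' background and, if requested, inserts a single spherical lesion of
#' intensity `tissue_level + lesion_contrast` whose radius is drawn
#' uniformly from `lesion_radius_range` and whose position is chosen so the
#' sphere lies fully inside the tissue region.
#'
#' @param params A [phantom_params()] object.
#' @param with_lesion Logical; insert a lesion (label 1) or not (label 0).
#' @param rng_seed Integer seed; identical seeds give voxelwise-identical
#'   volumes.
#' @return A list with components `volume` (3D array) and `label`
#'   (integer 0 = healthy / 1 = unhealthy).
#' @export
make_phantom <- function(params, with_lesion = FALSE, rng_seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  shp <- params$shape
  semi <- 0.45 * shp
  ctr <- (shp + 1) / 2
  # squared ellipsoid coordinate per axis, combined by outer sums
  q1 <- ((seq_len(shp[1]) - ctr[1]) / semi[1])^2
  q2 <- ((seq_len(shp[2]) - ctr[2]) / semi[2])^2
  q3 <- ((seq_len(shp[3]) - ctr[3]) / semi[3])^2
  qq <- outer(outer(q1, q2, `+`), q3, `+`)
  tissue <- qq <= 1
  vol <- array(params$background_level, dim = shp)
  vol[tissue] <- params$tissue_level

  if (with_lesion) {
    with_seed_local(rng_seed, {
      r <- runif(1, params$lesion_radius_range[1], params$lesion_radius_range[2])
      if (r > min(semi) - 1)
        stop_param(sprintf(
          "lesion of radius %.2f voxels cannot fit inside the tissue region (smallest semi-axis %.2f)",
          r, min(semi)))
      frac <- params$lesion_center_fraction %||% 1
      core <- qq <= frac^2
      if (!any(core)) core <- qq <= 1
      tissue_idx <- which(core, arr.ind = TRUE)
      placed <- FALSE
      for (try in seq_len(200)) {
        cen <- tissue_idx[sample.int(nrow(tissue_idx), 1L), ]
        # exact voxelized containment: every voxel within r of the center
        # must exist and be tissue
        rr <- ceiling(r)
        ylo <- cen[1] - rr; yhi <- cen[1] + rr
        xlo <- cen[2] - rr; xhi <- cen[2] + rr
        zlo <- cen[3] - rr; zhi <- cen[3] + rr
        if (ylo < 1 || xlo < 1 || zlo < 1 ||
            yhi > shp[1] || xhi > shp[2] || zhi > shp[3]) next
        ys <- ylo:yhi; xs <- xlo:xhi; zs <- zlo:zhi
        d1 <- (ys - cen[1])^2; d2 <- (xs - cen[2])^2; d3 <- (zs - cen[3])^2
        inside <- outer(outer(d1, d2, `+`), d3, `+`) <= r^2
        sub <- tissue[ys, xs, zs, drop = FALSE]
        if (all(sub[inside])) {
          # peritumoral edema: a graded hyperintense halo out to twice the
          # core radius, confined to tissue, decaying linearly from
          # edema_fraction * lesion_contrast at the core edge to zero
          hr <- ceiling(2 * r)
          hys <- max(1, cen[1] - hr):min(shp[1], cen[1] + hr)
          hxs <- max(1, cen[2] - hr):min(shp[2], cen[2] + hr)
          hzs <- max(1, cen[3] - hr):min(shp[3], cen[3] + hr)
          hd <- sqrt(outer(outer((hys - cen[1])^2, (hxs - cen[2])^2, `+`),
                           (hzs - cen[3])^2, `+`))
          efrac <- params$edema_fraction %||% 0.4
          halo_gain <- pmax(0, 1 - pmax(hd - r, 0) / r) * efrac * params$lesion_contrast
          hblock <- vol[hys, hxs, hzs, drop = FALSE]
          htis <- tissue[hys, hxs, hzs, drop = FALSE]
          sel <- htis & hd <= 2 * r & hd > r
          hblock[sel] <- params$tissue_level + halo_gain[sel]
          vol[hys, hxs, hzs] <- hblock
          block <- vol[ys, xs, zs, drop = FALSE]
          block[inside] <- params$tissue_level + params$lesion_contrast
          vol[ys, xs, zs] <- block
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_param(sprintf(
          "lesion of radius %.2f voxels cannot fit inside the tissue region", r))
    })
  }
  list(volume = vol, label = as.integer(with_lesion))
}

#' Add Rician magnitude noise to a volume
#'
#' MR magnitude images are the modulus of complex-valued measurements with
#' independent Gaussian noise in each channel, so each noisy voxel is
#' `sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`. At zero signal
#' this reduces to a Rayleigh distribution (mean `sigma * sqrt(pi/2)`); at
#' high signal-to-noise it approaches additive Gaussian noise.
#'
#' @param volume 3D array of nonnegative intensities.
#' @param sigma Standard deviation of each Gaussian channel; `0` returns the
#'   input unchanged.
#' @param rng_seed Integer seed.
#' @return A 3D array of the same shape with nonnegative intensities.
#' @export
add_rician_noise <- function(volume, sigma, rng_seed = 1L) {
  check_volume(volume)
  check_scalar_number(sigma, "sigma", lower = 0)
  if (sigma == 0) return(volume)
  with_seed_local(rng_seed, {
    n <- length(volume)
    out <- sqrt((volume + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    array(out, dim = dim(volume))
  })
}

#' Generate a labeled synthetic dataset
#'
#' Emits `n_healthy` lesion-free volumes followed by `n_lesion`
#' lesion-bearing volumes. Each phantom is built noiselessly and Rician
#' noise is applied once afterwards; all per-volume seeds derive from
#' `params$seed`, so the whole dataset is reproducible.
#'
#' @param n_healthy,n_lesion Nonnegative volume counts per class.
#' @param params A [phantom_params()] object.
#' @return A tibble with columns `id`, `label` (0/1) and `volume`
#'   (list-column of 3D arrays).
#' @export
generate_labeled_dataset <- function(n_healthy, n_lesion, params) {
  check_scalar_number(n_healthy, "n_healthy", lower = 0)
  check_scalar_number(n_lesion, "n_lesion", lower = 0)
  stopifnot(inherits(params, "phantom_params"))
  labels <- c(rep(0L, n_healthy), rep(1L, n_lesion))
  n <- length(labels)
  vols <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- make_phantom(params, with_lesion = labels[i] == 1L,
                       rng_seed = derive_seed(params$seed, 1L, i))
    vols[[i]] <- add_rician_noise(ph$volume, params$noise_sigma,
                                  rng_seed = derive_seed(params$seed, 2L, i))
  }
  tibble(id = sprintf("vol%03d", seq_len(n)), label = labels, volume = vols)
}

#' Generate an unlabeled source corpus
#'
#' Produces `n` volumes for autoencoder pretraining from a distribution that
#' deliberately differs from the target dataset: lesions occur with
#' probability `lesion_prevalence` (default 50%) and their radii are drawn
#' from a wider range, so transferring features across the domain gap is
#' nontrivial. Labels are generated internally but not returned.
#'
#' @param n Nonnegative corpus size.
#' @param params A [phantom_params()] object describing the base anatomy.
#' @param lesion_prevalence Probability that a corpus volume carries a
#'   lesion.
#' @param lesion_radius_range Radius range for corpus lesions; the default
#'   widens the target range on both sides, capped so lesions still fit the
#'   tissue region.
#' @return A tibble with columns `id` and `volume` (list-column).
#' @export
generate_source_corpus <- function(n, params,
                                   lesion_prevalence = 0.5,
                                   lesion_radius_range = NULL) {
  check_scalar_number(n, "n", lower = 0)
  stopifnot(inherits(params, "phantom_params"))
  check_scalar_number(lesion_prevalence, "lesion_prevalence", 0, 1)
  if (is.null(lesion_radius_range)) {
    rr <- params$lesion_radius_range
    min_semi <- min(0.45 * params$shape)
    lesion_radius_range <- c(max(1, 0.75 * rr[1]),
                             max(max(1, 0.75 * rr[1]), min(1.4 * rr[2], min_semi - 1)))
  }
  src_params <- params
  src_params$lesion_radius_range <- lesion_radius_range
  lesioned <- with_seed_local(derive_seed(params$seed, 9L),
                              runif(n) < lesion_prevalence)
  vols <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- make_phantom(src_params, with_lesion = isTRUE(lesioned[i]),
                       rng_seed = derive_seed(params$seed, 3L, i))
    vols[[i]] <- add_rician_noise(ph$volume, params$noise_sigma,
                                  rng_seed = derive_seed(params$seed, 4L, i))
  }
  tibble(id = sprintf("src%03d", seq_len(n)), volume = vols)
}
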