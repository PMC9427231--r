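#' Assemble a full run configuration
#'
#' Bundles every stage's parameters — phantom generation, window coverage,
#' augmentation, autoencoder, classifier, evaluation protocol — with a
#' master seed and an output directory, as one serializable object. Every
#' random operation in a run derives its seed from `seed`.
#'
#' @param phantom A [phantom_params()] object.
#' @param coverage Window coverage fraction.
#' @param augment An [augmentation_config()] object.
#' @param autoencoder An [autoencoder_config()] object.
#' @param classifier A [classifier_config()] object.
#' @param repeats Grid-search repeat count.
#' @param full_grid Use the full 27-point grid instead of the 9-point
#'   pairing.
#' @param seed Master seed.
#' @param out_dir Output directory for CLI runs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_params(),
                       coverage = 0.95,
                       augment = augmentation_config(),
                       autoencoder = autoencoder_config(),
                       classifier = classifier_config(),
                       repeats = 15L,
                       full_grid = FALSE,
                       seed = 1L,
                       out_dir = "phantomnet-out") {
  stopifnot(inherits(phantom, "phantom_params"),
            inherits(augment, "augmentation_config"),
            inherits(autoencoder, "autoencoder_config"),
            inherits(classifier, "classifier_config"))
  check_scalar_number(coverage, "coverage", 1e-12, 1)
  check_scalar_number(repeats, "repeats", lower = 1)
  structure(list(phantom = phantom, coverage = coverage, augment = augment,
                 autoencoder = autoencoder, classifier = classifier,
                 repeats = as.integer(repeats), full_grid = isTRUE(full_grid),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config A [run_config()] object.
#' @param path Destination `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path, precision = 15)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Values are revalidated through the stage constructors, so a tampered or
#' out-of-range file fails loudly; the result round-trips losslessly
#' through [write_run_config()].
#'
#' @param path A `.yaml` file written by [write_run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  needed <- c("phantom", "coverage", "augment", "autoencoder", "classifier",
              "repeats", "full_grid", "seed", "out_dir")
  if (!all(needed %in% names(raw)))
    stop_format(sprintf("%s is not a phantomnet run configuration", path))
  ctor <- function(f, args)
    do.call(f, args[intersect(names(args), names(formals(f)))])
  run_config(
    phantom = ctor(phantom_params, raw$phantom),
    coverage = raw$coverage,
    augment = ctor(augmentation_config, raw$augment),
    autoencoder = ctor(autoencoder_config, raw$autoencoder),
    classifier = ctor(classifier_config, raw$classifier),
    repeats = raw$repeats,
    full_grid = raw$full_grid,
    seed = raw$seed,
    out_dir = raw$out_dir)
}
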