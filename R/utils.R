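# Internal helpers: seeded evaluation, seed derivation, validation.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All randomized operations in the
# package run through this, so a master seed pins every result.
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed derivation: fold a master seed and a tuple of counters
# (config index, repeat, fold, ...) into a new 31-bit seed with an LCG-style
# mix. Keeps every product below 2^53 so the arithmetic is exact.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483629
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 101 + 1) %% 2147483629
  }
  as.integer(s + 1)
}

stop_param <- function(msg) abort(msg, class = "phantomnet_param_error")
stop_shape <- function(msg) abort(msg, class = "phantomnet_shape_error")
stop_input <- function(msg) abort(msg, class = "phantomnet_input_error")
stop_io    <- function(msg) abort(msg, class = "phantomnet_io_error")
stop_format <- function(msg) abort(msg, class = "phantomnet_format_error")
stop_config <- function(msg) abort(msg, class = "phantomnet_config_error")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop_param(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

check_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_shape(sprintf("`%s` must be a 3D array, got rank %d",
                       name, if (is.array(x)) length(dim(x)) else 1L))
  if (!all(is.finite(x)))
    stop_input(sprintf("`%s` contains non-finite intensities", name))
  invisible(x)
}

# Accept a bare list of 3D arrays or a dataset tibble with a `volume`
# list-column; return the list of arrays.
as_volume_list <- function(x, name = "volumes") {
  if (is.data.frame(x)) {
    if (!"volume" %in% names(x))
      stop_input(sprintf("`%s` data frame must have a `volume` list-column", name))
    x <- x$volume
  }
  if (!is.list(x) || length(x) == 0L)
    stop_input(sprintf("`%s` must be a non-empty list of 3D arrays", name))
  x
}

fmt_shape <- function(d) paste(d, collapse = "x")
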