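# Internal neural-network engine. Convolutions are 3x3x3, stride 1, zero
# ("same") padding, computed by direct C++ kernels; dense layers are BLAS
# products. Activations travel as (B*N) x channels matrices (N = voxels per
# volume, B = minibatch size, sample-major row blocks); arrays appear only
# at the interfaces. Optimization is Adam on a flat named list of tensors.

relu <- function(x) pmax(x, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct convolution wrappers (C++ kernels; no im2col materialization).
# a_mat is (B*N) x Cin, sample-major row blocks.
conv_fwd_batch <- function(a_mat, spatial, B, W, b, act = TRUE) {
  conv3_direct(a_mat, as.integer(spatial), as.integer(B), W, b, act)
}

conv_bwd_batch <- function(a_in, dz, spatial, B, W) {
  cin <- ncol(a_in)
  list(dW = array(conv3_grad_w(a_in, dz, as.integer(spatial), as.integer(B)),
                  dim = dim(W)),
       db = colSums(dz),
       dx = conv3_grad_x(dz, as.integer(spatial), as.integer(B), W, cin))
}

# He-style seeded initialization for one kernel tensor
init_kernel <- function(k1, k2, k3, cin, cout, fan_in) {
  array(rnorm(k1 * k2 * k3 * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(k1, k2, k3, cin, cout))
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# Per-tensor learning-rate multipliers: adaptive (per-weight normalized)
# updates move a unit's pre-activation in proportion to its fan-in, so the
# very wide flatten->dense weight matrix must step more slowly than the
# small convolution kernels or its ReLU units saturate within a few
# updates. Width-robust parametrizations scale the dense-layer rate by
# 1/fan-in; `lr_ref` sets the fan-in at which the multiplier reaches 1.
lr_multipliers <- function(params, lr_ref = 2048) {
  mult <- rep(1, length(params))
  names(mult) <- names(params)
  for (nm in names(params)) {
    if (endsWith(nm, ".W")) {
      d <- dim(params[[nm]])
      fan_in <- if (length(d) == 5L) 27 * d[4] else d[1]
      mult[nm] <- min(1, lr_ref / fan_in)
    }
  }
  mult
}

adam_step <- function(params, grads, state, lr, t, mult = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    lr_nm <- if (is.null(mult)) lr else lr * mult[[nm]]
    upd <- adam_fused(params[[nm]], grads[[nm]], state[[nm]]$m, state[[nm]]$v,
                      lr_nm, beta1, beta2, eps, t)
    params[[nm]] <- upd$p
    state[[nm]] <- list(m = upd$m, v = upd$v)
  }
  list(params = params, state = state)
}

# Stack a list of volumes into the (B*N) x 1 sample-major activation matrix
stack_volumes <- function(vols) {
  matrix(unlist(lapply(vols, as.numeric), use.names = FALSE), ncol = 1)
}

# ---- classifier network -----------------------------------------------------

# params: conv_i.W / conv_i.b per layer, fc.W, fc.b, out.W, out.b
classifier_init_params <- function(config, input_shape) {
  filters <- config$filters
  cin <- 1L
  params <- list()
  for (i in seq_along(filters)) {
    params[[sprintf("conv%d.W", i)]] <-
      init_kernel(3, 3, 3, cin, filters[i], fan_in = 27 * cin)
    params[[sprintf("conv%d.b", i)]] <- numeric(filters[i])
    cin <- filters[i]
  }
  nflat <- prod(input_shape) * cin
  params[["fc.W"]] <- matrix(rnorm(nflat * config$fc_nodes, sd = sqrt(2 / nflat)),
                             nflat, config$fc_nodes)
  params[["fc.b"]] <- numeric(config$fc_nodes)
  # small output weights start the sigmoid near 0.5, avoiding a coherent
  # early push that can silence the ReLU layer under adaptive updates
  params[["out.W"]] <- matrix(rnorm(config$fc_nodes, sd = 0.05),
                              config$fc_nodes, 1)
  params[["out.b"]] <- 0
  params
}

# vols: list of 3D arrays (a minibatch). Returns p (length B) and caches.
#
# Between flatten and the dense layer sits a non-trainable centering step:
# during training each flatten feature is centered on its minibatch mean
# (running mean tracked for inference), removing the large shared
# anatomical component of the activations. Without it the dense-layer
# optimization is ill-conditioned: the common component dwarfs the
# between-class differences and gradient training stalls or collapses.
# `center` is the running-mean vector (NULL = zeros); `batch_center = TRUE`
# uses the minibatch mean instead (training mode, needs B >= 2).
classifier_forward <- function(params, config, input_shape, vols,
                               keep_cache = FALSE, center = NULL,
                               batch_center = FALSE) {
  if (is.array(vols)) vols <- list(vols)
  B <- length(vols)
  N <- prod(input_shape)
  a <- stack_volumes(vols)
  n_layers <- config$n_conv_layers
  cache <- if (keep_cache) list(acts = vector("list", n_layers),
                                ins = vector("list", n_layers)) else NULL
  cin <- 1L
  for (i in seq_len(n_layers)) {
    cout <- config$filters[i]
    if (keep_cache) cache$ins[[i]] <- a
    a <- conv_fwd_batch(a, input_shape, B,
                        params[[sprintf("conv%d.W", i)]],
                        params[[sprintf("conv%d.b", i)]], act = TRUE)
    if (keep_cache) cache$acts[[i]] <- a
    cin <- cout
  }
  # flatten: sample s occupies rows (s-1)*N+1 .. s*N; its flat vector is the
  # column-major read of its N x Cin block. One permutation handles the batch.
  flatM <- if (B == 1L) matrix(as.numeric(a), 1L)
           else matrix(aperm(array(a, c(N, B, cin)), c(2L, 1L, 3L)), B)
  use_batch <- batch_center && B >= 2L
  ctr <- if (use_batch) colMeans(flatM)
         else if (!is.null(center)) center else numeric(ncol(flatM))
  flatC <- flatM - rep(ctr, each = B)
  hM <- relu(flatC %*% params$fc.W + rep(params$fc.b, each = B))
  z <- drop(hM %*% params$out.W) + params$out.b
  p <- sigmoid(z)
  if (keep_cache) {
    cache$flatM <- flatM; cache$flatC <- flatC; cache$hM <- hM; cache$p <- p
    cache$B <- B; cache$cin_last <- cin; cache$batch_centered <- use_batch
  }
  list(p = p, cache = cache, batch_mean = if (use_batch) ctr else NULL)
}

# Gradients of the SUMMED binary cross-entropy over the batch.
classifier_backward <- function(params, config, input_shape, cache, y) {
  B <- cache$B
  N <- prod(input_shape)
  dz <- matrix(cache$p - y, ncol = 1)
  grads <- list()
  grads[["out.W"]] <- crossprod(cache$hM, dz)
  grads[["out.b"]] <- sum(dz)
  dhM <- (dz %*% t(params$out.W)) * (cache$hM > 0)
  grads[["fc.W"]] <- crossprod(cache$flatC, dhM)
  grads[["fc.b"]] <- colSums(dhM)
  dflatM <- tcrossprod(dhM, params$fc.W)
  if (isTRUE(cache$batch_centered)) {
    # adjoint of per-feature batch-mean centering
    dflatM <- dflatM - rep(colMeans(dflatM), each = B)
  }
  cin <- cache$cin_last
  da <- matrix(aperm(array(dflatM, c(B, N, cin)), c(2L, 1L, 3L)), B * N, cin)
  for (i in rev(seq_len(config$n_conv_layers))) {
    dzc <- da * (cache$acts[[i]] > 0)
    W <- params[[sprintf("conv%d.W", i)]]
    bw <- conv_bwd_batch(cache$ins[[i]], dzc, input_shape, B, W)
    grads[[sprintf("conv%d.W", i)]] <- bw$dW
    grads[[sprintf("conv%d.b", i)]] <- bw$db
    if (i > 1L) da <- bw$dx
  }
  grads
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# ---- autoencoder network ----------------------------------------------------

# Encoder: conv layers 1 -> f1 -> ... -> fL, ReLU; decoder mirrors it:
# fL -> f(L-1) -> ... -> f1 -> 1 with ReLU on all but the final (linear) layer.
ae_layer_channels <- function(encoder_filters) {
  L <- length(encoder_filters)
  list(enc_in = c(1L, head(encoder_filters, -1)),
       enc_out = encoder_filters,
       dec_in = rev(encoder_filters),
       dec_out = c(rev(head(encoder_filters, -1)), 1L),
       L = L)
}

ae_init_params <- function(config) {
  ch <- ae_layer_channels(config$encoder_filters)
  params <- list()
  for (i in seq_len(ch$L)) {
    params[[sprintf("enc%d.W", i)]] <-
      init_kernel(3, 3, 3, ch$enc_in[i], ch$enc_out[i], fan_in = 27 * ch$enc_in[i])
    params[[sprintf("enc%d.b", i)]] <- numeric(ch$enc_out[i])
  }
  for (i in seq_len(ch$L)) {
    params[[sprintf("dec%d.W", i)]] <-
      init_kernel(3, 3, 3, ch$dec_in[i], ch$dec_out[i], fan_in = 27 * ch$dec_in[i])
    params[[sprintf("dec%d.b", i)]] <- numeric(ch$dec_out[i])
  }
  params
}

# x_mat: (B*N) x 1 stacked patches
ae_forward <- function(params, config, patch_shape, x_mat, B,
                       keep_cache = FALSE) {
  ch <- ae_layer_channels(config$encoder_filters)
  names_all <- c(sprintf("enc%d", seq_len(ch$L)), sprintf("dec%d", seq_len(ch$L)))
  cin_all <- c(ch$enc_in, ch$dec_in)
  cout_all <- c(ch$enc_out, ch$dec_out)
  relu_all <- c(rep(TRUE, ch$L), rep(TRUE, ch$L - 1), FALSE)
  a <- x_mat
  cache <- if (keep_cache) list(acts = list(), ins = list(),
                                relu = relu_all, B = B) else NULL
  for (i in seq_along(names_all)) {
    if (keep_cache) cache$ins[[i]] <- a
    a <- conv_fwd_batch(a, patch_shape, B,
                        params[[paste0(names_all[i], ".W")]],
                        params[[paste0(names_all[i], ".b")]],
                        act = relu_all[i])
    if (keep_cache) cache$acts[[i]] <- a
  }
  list(xhat = a, cache = cache)
}

# Gradients of the SUMMED per-patch voxel-mean squared error.
ae_backward <- function(params, config, patch_shape, cache, x_mat) {
  ch <- ae_layer_channels(config$encoder_filters)
  names_all <- c(sprintf("enc%d", seq_len(ch$L)), sprintf("dec%d", seq_len(ch$L)))
  n_all <- length(names_all)
  B <- cache$B
  N <- prod(patch_shape)
  da <- 2 * (cache$acts[[n_all]] - x_mat) / N
  grads <- list()
  for (i in rev(seq_len(n_all))) {
    dz <- if (cache$relu[i]) da * (cache$acts[[i]] > 0) else da
    W <- params[[paste0(names_all[i], ".W")]]
    bw <- conv_bwd_batch(cache$ins[[i]], dz, patch_shape, B, W)
    grads[[paste0(names_all[i], ".W")]] <- bw$dW
    grads[[paste0(names_all[i], ".b")]] <- bw$db
    if (i > 1L) da <- bw$dx
  }
  grads
}
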