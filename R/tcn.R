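# Three-branch temporal convolutional network: per-branch stacks of causal
# dilated convolutions (conv -> LeakyReLU -> LayerNorm) whose outputs are
# fused by one linear map into the per-frame local feature vector.

#' TCN configuration
#'
#' Five causal convolution layers per branch with the dilation schedule
#' `[1, 2, 4, 8, 16]`. The default kernel size is 2, which makes the stack's
#' receptive field match the design intent exactly: 2 frames at dilation 1,
#' growing to 32 frames over the full stack (`1 + (K-1) * sum(dilations)`).
#' A kernel of 3 taps is also in circulation for this architecture but breaks
#' that receptive-field arithmetic; it remains available via `kernel_size`.
#'
#' @param kernel_size Taps per convolution kernel (default 2).
#' @param dilations Integer dilation per layer (default `c(1, 2, 4, 8, 16)`).
#' @param channels Channels per branch in every layer (default 128).
#' @param out_dim Fused local feature dimension (default 256).
#' @param leaky_slope LeakyReLU negative slope (default 0.1).
#' @return A list of class `tcn_config`.
#' @export
tcn_config <- function(kernel_size = 2, dilations = c(1, 2, 4, 8, 16),
                       channels = 128, out_dim = 256, leaky_slope = 0.1) {
  stop_if(!is_count(kernel_size), "kernel_size must be a positive integer")
  stop_if(any(dilations < 1) || any(dilations != round(dilations)),
          "dilations must be positive integers")
  structure(list(kernel_size = as.integer(kernel_size),
                 dilations = as.integer(dilations),
                 n_layers = length(dilations),
                 channels = as.integer(channels),
                 out_dim = as.integer(out_dim),
                 leaky_slope = leaky_slope),
            class = "tcn_config")
}

#' Receptive field of the causal dilated stack
#'
#' Number of past input frames (inclusive of the current one) that influence
#' one output frame after the whole stack: `1 + (K - 1) * sum(dilations)`.
#' With the default kernel of 2 and dilations 1..16 this is 32 frames; the
#' first layer alone spans `1 + (K - 1) * d1` = 2 frames.
#'
#' @param cfg A [tcn_config()].
#' @param layers Optionally, use only the first `layers` dilations.
#' @return Receptive field in frames.
#' @export
tcn_receptive_field <- function(cfg = tcn_config(), layers = cfg$n_layers) {
  1L + (cfg$kernel_size - 1L) * sum(cfg$dilations[seq_len(layers)])
}

#' Initialize TCN parameters
#'
#' Independent weights for the three branches (joint, bone, velocity) plus
#' the fusion linear map `3 * channels -> out_dim`.
#'
#' @param cfg A [tcn_config()].
#' @param in_dims Input widths of the three branches (default joint 75,
#'   bone 72, velocity 75).
#' @param seed Seed for the initialization.
#' @return A parameter list of class `tcn_params` (the config is carried
#'   along in `$cfg`).
#' @export
tcn_init <- function(cfg = tcn_config(), in_dims = c(75L, 72L, 75L), seed = 1) {
  with_seed(seed, {
    branches <- lapply(in_dims, function(d_in) {
      lapply(seq_len(cfg$n_layers), function(l) {
        n_in <- if (l == 1L) d_in else cfg$channels
        list(conv = conv_init(n_in, cfg$channels, cfg$kernel_size),
             ln = ln_init(cfg$channels))
      })
    })
    structure(list(branches = branches,
                   fusion = linear_init(3L * cfg$channels, cfg$out_dim),
                   cfg = cfg),
              class = "tcn_params")
  })
}

#' TCN forward pass
#'
#' Runs the three branch stacks (each layer: causal dilated convolution,
#' LeakyReLU, LayerNorm) on the joint/bone/velocity streams, concatenates
#' the branch outputs per frame and fuses them linearly into the local
#' feature sequence. The output at frame t depends only on inputs at frames
#' `<= t`.
#'
#' @param params A [tcn_init()] parameter list.
#' @param branches A [branch_features()] list (elements `joint`, `bone`,
#'   `velocity`, all with the same number of rows).
#' @return A T x out_dim matrix of local features.
#' @export
tcn_forward <- function(params, branches) {
  tcn_fwd(params, branches)$local
}

tcn_fwd <- function(params, branches) {
  cfg <- params$cfg
  streams <- list(branches$joint, branches$bone, branches$velocity)
  nT <- unique(vapply(streams, nrow, integer(1)))
  stop_if(length(nT) != 1L, "branch streams must share the same length")
  caches <- vector("list", 3L)
  outs <- vector("list", 3L)
  for (b in 1:3) {
    x <- streams[[b]]
    layer_caches <- vector("list", cfg$n_layers)
    for (l in seq_len(cfg$n_layers)) {
      lp <- params$branches[[b]][[l]]
      z <- conv_fwd(x, lp$conv$W, lp$conv$b, cfg$dilations[l])
      a <- leaky_relu(z, cfg$leaky_slope)
      lnc <- ln_fwd(a, lp$ln)
      layer_caches[[l]] <- list(x = x, z = z, ln = lnc)
      x <- lnc$y
    }
    caches[[b]] <- layer_caches
    outs[[b]] <- x
  }
  concat <- cbind(outs[[1]], outs[[2]], outs[[3]])
  local <- linear_fwd(concat, params$fusion)
  list(local = local, concat = concat, caches = caches)
}

tcn_bwd <- function(params, cache, dlocal) {
  cfg <- params$cfg
  fus <- linear_bwd(cache$concat, params$fusion, dlocal)
  C <- cfg$channels
  grads <- list(branches = vector("list", 3L),
                fusion = list(W = fus$dW, b = fus$db))
  for (b in 1:3) {
    dx <- fus$dx[, ((b - 1) * C + 1):(b * C), drop = FALSE]
    layer_grads <- vector("list", cfg$n_layers)
    for (l in rev(seq_len(cfg$n_layers))) {
      lp <- params$branches[[b]][[l]]
      lc <- cache$caches[[b]][[l]]
      g_ln <- ln_bwd(dx, lc$ln, lp$ln)
      dz <- g_ln$dx * leaky_relu_grad(lc$z, cfg$leaky_slope)
      g_cv <- conv_bwd(lc$x, lp$conv$W, cfg$dilations[l], dz)
      layer_grads[[l]] <- list(conv = list(W = g_cv$dW, b = g_cv$db),
                               ln = list(gamma = g_ln$dgamma, beta = g_ln$dbeta))
      dx <- g_cv$dx
    }
    grads$branches[[b]] <- layer_grads
  }
  grads
}
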