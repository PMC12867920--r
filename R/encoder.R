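# Attention encoder: linear lift of the local features to the model
# dimension, fixed sinusoidal positional encoding, then a stack of post-norm
# encoder layers (multi-head self-attention -> Add & Norm -> GELU
# feed-forward -> Add & Norm, with dropout), plus temporal mean pooling into
# a single global feature vector.

#' Encoder configuration
#'
#' @param n_layers Number of encoder layers (default 3).
#' @param heads Attention heads per layer (default 8); must divide
#'   `model_dim` (per-head dimension `d_k = model_dim / heads`, 64 at the
#'   defaults).
#' @param model_dim Global feature dimension (default 512).
#' @param ffn_dim Feed-forward hidden width (default 2048, i.e.
#'   512 -> 2048 -> 512).
#' @param input_dim Width of the incoming local features (default 256).
#' @param dropout Dropout rate applied after attention and feed-forward
#'   blocks during training (default 0.1).
#' @param positional Add the fixed sinusoidal positional encoding after the
#'   input lift (default `TRUE`; without it mean pooling makes the encoder
#'   permutation-invariant over frames).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 3, heads = 8, model_dim = 512,
                           ffn_dim = 2048, input_dim = 256, dropout = 0.1,
                           positional = TRUE) {
  stop_if(model_dim %% heads != 0, "model_dim must be divisible by heads")
  stop_if(n_layers < 1, "need at least one encoder layer")
  structure(list(n_layers = as.integer(n_layers), heads = as.integer(heads),
                 model_dim = as.integer(model_dim),
                 head_dim = as.integer(model_dim / heads),
                 ffn_dim = as.integer(ffn_dim),
                 input_dim = as.integer(input_dim),
                 dropout = dropout, positional = isTRUE(positional)),
            class = "encoder_config")
}

#' Initialize encoder parameters
#'
#' @param cfg An [encoder_config()].
#' @param seed Seed for the initialization.
#' @return A parameter list of class `encoder_params` carrying `cfg`.
#' @export
encoder_init <- function(cfg = encoder_config(), seed = 1) {
  with_seed(seed, {
    D <- cfg$model_dim
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      list(attn = list(Wq = lapply(seq_len(cfg$heads), function(i) glorot(D, cfg$head_dim)),
                       Wk = lapply(seq_len(cfg$heads), function(i) glorot(D, cfg$head_dim)),
                       Wv = lapply(seq_len(cfg$heads), function(i) glorot(D, cfg$head_dim)),
                       Wo = glorot(D, D)),
           ln1 = ln_init(D),
           ffn = list(W1 = glorot(D, cfg$ffn_dim), b1 = rep(0, cfg$ffn_dim),
                      W2 = glorot(cfg$ffn_dim, D), b2 = rep(0, D)),
           ln2 = ln_init(D))
    })
    structure(list(lift = linear_init(cfg$input_dim, D), layers = layers,
                   cfg = cfg),
              class = "encoder_params")
  })
}

#' Encoder forward pass
#'
#' Lifts the T x input_dim local features to the model dimension, optionally
#' adds the positional encoding, applies the encoder layers, and returns the
#' global feature sequence together with its temporal mean-pooled summary
#' vector. With `training = FALSE` (the default) dropout is disabled and the
#' pass is fully deterministic.
#'
#' @param params An [encoder_init()] parameter list.
#' @param x T x input_dim matrix of local features.
#' @param training Enable dropout (draws from the current RNG state).
#' @return A list with `seq` (T x model_dim) and `pooled` (model_dim vector).
#' @export
encoder_forward <- function(params, x, training = FALSE) {
  out <- enc_fwd(params, x, training)
  list(seq = out$y, pooled = out$pooled)
}

enc_fwd <- function(params, x, training = FALSE) {
  cfg <- params$cfg
  stop_if(ncol(x) != cfg$input_dim, "local feature width must equal input_dim")
  h <- linear_fwd(x, params$lift)
  if (cfg$positional) h <- h + positional_encoding(nrow(h), cfg$model_dim)
  layer_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    att <- mha_fwd(h, lp$attn)
    d1 <- dropout_fwd(att$y, cfg$dropout, training)
    r1 <- h + d1$y
    n1 <- ln_fwd(r1, lp$ln1)
    f1 <- t(t(n1$y %*% lp$ffn$W1) + lp$ffn$b1)
    g <- gelu(f1)
    f2 <- t(t(g %*% lp$ffn$W2) + lp$ffn$b2)
    d2 <- dropout_fwd(f2, cfg$dropout, training)
    r2 <- n1$y + d2$y
    n2 <- ln_fwd(r2, lp$ln2)
    layer_caches[[l]] <- list(x = h, att = att, d1 = d1, n1 = n1,
                              f1 = f1, g = g, d2 = d2, n2 = n2)
    h <- n2$y
  }
  list(y = h, pooled = colMeans(h), x_in = x, caches = layer_caches)
}

# Backward pass; dseq and/or dpooled may be NULL.
enc_bwd <- function(params, cache, dseq = NULL, dpooled = NULL) {
  cfg <- params$cfg
  nT <- nrow(cache$y)
  dh <- if (is.null(dseq)) matrix(0, nT, cfg$model_dim) else dseq
  if (!is.null(dpooled)) {
    dh <- dh + matrix(dpooled / nT, nT, cfg$model_dim, byrow = TRUE)
  }
  layer_grads <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    lc <- cache$caches[[l]]
    g2 <- ln_bwd(dh, lc$n2, lp$ln2)
    dr2 <- g2$dx
    df2 <- dropout_bwd(dr2, lc$d2$mask)
    dW2 <- crossprod(lc$g, df2); db2 <- colSums(df2)
    dg <- df2 %*% t(lp$ffn$W2)
    df1 <- dg * gelu_grad(lc$f1)
    dW1 <- crossprod(lc$n1$y, df1); db1 <- colSums(df1)
    dn1y <- dr2 + df1 %*% t(lp$ffn$W1)
    g1 <- ln_bwd(dn1y, lc$n1, lp$ln1)
    dr1 <- g1$dx
    datt <- dropout_bwd(dr1, lc$d1$mask)
    ga <- mha_bwd(lc$x, lp$attn, lc$att, datt)
    dh <- dr1 + ga$dx
    layer_grads[[l]] <- list(
      attn = list(Wq = ga$dWq, Wk = ga$dWk, Wv = ga$dWv, Wo = ga$dWo),
      ln1 = list(gamma = g1$dgamma, beta = g1$dbeta),
      ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
      ln2 = list(gamma = g2$dgamma, beta = g2$dbeta))
  }
  lift <- linear_bwd(cache$x_in, params$lift, dh)
  list(lift = list(W = lift$dW, b = lift$db), layers = layer_grads,
       dx_in = lift$dx)
}
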