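# Neural-network primitives with hand-derived backward passes. Parameters are
# plain lists of matrices; every *_fwd returns the values needed by the
# matching *_bwd. Analytic gradients are verified against finite differences
# in the test suite.

# ---- activations ----------------------------------------------------------

#' LeakyReLU activation
#'
#' `x` for `x >= 0`, `alpha * x` otherwise. The small negative slope keeps
#' gradient flowing through weakly activated units (default `alpha = 0.1`).
#'
#' @param x Numeric vector, matrix or array.
#' @param alpha Negative-region slope in `(0, 1)`.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, alpha = 0.1) {
  stop_if(!(alpha > 0 && alpha < 1), "alpha must lie in (0, 1)")
  ifelse(x >= 0, x, alpha * x)
}

leaky_relu_grad <- function(x, alpha = 0.1) ifelse(x >= 0, 1, alpha)

#' GELU activation
#'
#' Gaussian error linear unit, `x * pnorm(x)`: a smooth weighting of the input
#' by the standard normal CDF.
#'
#' @param x Numeric vector, matrix or array.
#' @return Same shape as `x`.
#' @export
gelu <- function(x) x * pnorm(x)

gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer normalization --------------------------------------------------

#' Layer normalization
#'
#' Normalizes over the channel dimension: `gamma * (x - mu) / sqrt(var + eps)
#' + beta`, with the mean and (population) variance computed per time step
#' across channels. Adapts feature distributions across performers and styles
#' so per-sample features stay comparable.
#'
#' @param x Numeric vector (one channel vector) or T x C matrix (one row per
#'   time step).
#' @param gamma,beta Per-channel scale and shift (scalars broadcast).
#' @param eps Variance floor (default 1e-5).
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, gamma = 1, beta = 0, eps = 1e-5) {
  if (is.matrix(x)) {
    ln_fwd(x, list(gamma = rep_len(gamma, ncol(x)),
                   beta = rep_len(beta, ncol(x)), eps = eps))$y
  } else {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    gamma * (x - mu) / sqrt(v + eps) + beta
  }
}

ln_init <- function(dim) list(gamma = rep(1, dim), beta = rep(0, dim), eps = 1e-5)

ln_fwd <- function(x, p) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + p$eps)
  xhat <- xc * inv
  y <- t(t(xhat) * p$gamma + p$beta)
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- t(t(dy) * p$gamma)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- linear layer ---------------------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

linear_init <- function(n_in, n_out) list(W = glorot(n_in, n_out), b = rep(0, n_out))

linear_fwd <- function(x, p) t(t(x %*% p$W) + p$b)

linear_bwd <- function(x, p, dy) {
  list(dx = dy %*% t(p$W), dW = crossprod(x, dy), db = colSums(dy))
}

# ---- causal dilated convolution ------------------------------------------

#' Causal dilated convolution
#'
#' Computes `y_t = sum_{k=0}^{K-1} w_k . x_{t - d k}`, where `d` is the
#' dilation rate: the output at time `t` depends only on inputs at times
#' `<= t`, with positions before the first frame zero-padded. `weights` may be
#' a length-`K` numeric vector (one scalar tap shared by every channel) or a
#' `K x C_in x C_out` array of full tap matrices.
#'
#' @param x Numeric vector or T x C matrix of input features.
#' @param weights Kernel taps, nearest-in-time first.
#' @param dilation Positive integer dilation rate.
#' @param bias Optional per-output-channel bias.
#' @return Output of the same length / row count as `x`.
#' @export
#' @examples
#' causal_dilated_conv(c(1, 2, 3, 4), weights = c(1, 1, 1))  # 1 3 6 9
causal_dilated_conv <- function(x, weights, dilation = 1, bias = NULL) {
  stop_if(!(is_count(dilation)), "dilation must be a positive integer")
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, ncol = 1)
  if (is.numeric(weights) && is.null(dim(weights))) {
    W <- lapply(weights, function(w) diag(w, ncol(x)))
  } else {
    stop_if(length(dim(weights)) != 3L, "weights must be a vector or K x C_in x C_out array")
    W <- lapply(seq_len(dim(weights)[1]), function(k)
      matrix(weights[k, , ], dim(weights)[2], dim(weights)[3]))
  }
  y <- conv_fwd(x, W, bias %||% rep(0, ncol(W[[1]])), dilation)
  if (vec_in) drop(y) else y
}

conv_init <- function(n_in, n_out, K) {
  lim <- sqrt(6 / (K * n_in + n_out))
  list(W = lapply(seq_len(K), function(k)
         matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)),
       b = rep(0, n_out))
}

conv_fwd <- function(x, W, b, d) {
  y <- shift_rows(x, 0L) %*% W[[1]]
  for (k in seq_along(W)[-1]) {
    y <- y + shift_rows(x, d * (k - 1L)) %*% W[[k]]
  }
  t(t(y) + b)
}

conv_bwd <- function(x, W, d, dy) {
  dW <- vector("list", length(W))
  dx <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(W)) {
    s <- d * (k - 1L)
    dW[[k]] <- crossprod(shift_rows(x, s), dy)
    dx <- dx + unshift_rows(dy %*% t(W[[k]]), s)
  }
  list(dx = dx, dW = dW, db = colSums(dy))
}

# ---- attention ------------------------------------------------------------

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, row-wise: each query position receives a
#' convex combination of the value rows, with the `sqrt(d_k)` scaling keeping
#' the logits in a range where softmax retains gradient.
#'
#' @param Q,K,V Numeric matrices with conformable shapes (`Q`: n x d_k, `K`:
#'   m x d_k, `V`: m x d_v).
#' @return A list with `output` (n x d_v) and `weights` (n x m, rows sum
#'   to 1).
#' @export
scaled_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  dk <- ncol(K)
  stop_if(dk == 0L, "d_k must be positive")
  stop_if(ncol(Q) != dk || nrow(K) != nrow(V), "non-conformable attention shapes")
  W <- softmax_rows(Q %*% t(K) / sqrt(dk))
  list(output = W %*% V, weights = W)
}

attn_bwd <- function(Q, K, V, W, dO) {
  dk <- ncol(K)
  dV <- crossprod(W, dO)
  dWmat <- dO %*% t(V)
  dS <- W * (dWmat - rowSums(dWmat * W))
  list(dQ = dS %*% K / sqrt(dk), dK = crossprod(dS, Q) / sqrt(dk), dV = dV)
}

#' Multi-head self-attention specification
#'
#' Initializes the per-head query/key/value projections and the output mixing
#' matrix for `heads` parallel scaled dot-product attention maps over a
#' `model_dim`-dimensional sequence; `model_dim` must be divisible by `heads`
#' (head dimension `d_k = model_dim / heads`).
#'
#' @param heads Number of attention heads (default 8).
#' @param model_dim Model dimension (default 512).
#' @param dropout Dropout rate stored with the spec (applied inside the
#'   encoder, not by [multi_head()] itself).
#' @param seed Seed for the weight initialization.
#' @return A list of class `attention_spec` with fields `heads`, `model_dim`,
#'   `head_dim` and weight lists `Wq`, `Wk`, `Wv` (per head) and `Wo`.
#' @export
attention_spec <- function(heads = 8, model_dim = 512, dropout = 0.1, seed = 1) {
  stop_if(model_dim %% heads != 0, "model_dim must be divisible by heads")
  dk <- model_dim / heads
  with_seed(seed, {
    structure(list(
      heads = as.integer(heads), model_dim = as.integer(model_dim),
      head_dim = as.integer(dk), dropout = dropout,
      Wq = lapply(seq_len(heads), function(i) glorot(model_dim, dk)),
      Wk = lapply(seq_len(heads), function(i) glorot(model_dim, dk)),
      Wv = lapply(seq_len(heads), function(i) glorot(model_dim, dk)),
      Wo = glorot(model_dim, model_dim)
    ), class = "attention_spec")
  })
}

#' Multi-head self-attention
#'
#' Runs `heads` parallel scaled dot-product attention maps over learned
#' projections of `x`, concatenates the head outputs and mixes them with the
#' output matrix.
#'
#' @param x T x model_dim input matrix.
#' @param spec An [attention_spec()].
#' @return T x model_dim output matrix.
#' @export
multi_head <- function(x, spec) {
  stop_if(ncol(x) != spec$model_dim, "input width must equal model_dim")
  mha_fwd(x, spec)$y
}

mha_fwd <- function(x, p) {
  h <- length(p$Wq)
  heads <- vector("list", h)
  concat <- matrix(0, nrow(x), ncol(p$Wo))
  dk <- ncol(p$Wq[[1]])
  for (i in seq_len(h)) {
    Q <- x %*% p$Wq[[i]]; K <- x %*% p$Wk[[i]]; V <- x %*% p$Wv[[i]]
    W <- softmax_rows(Q %*% t(K) / sqrt(dk))
    O <- W %*% V
    heads[[i]] <- list(Q = Q, K = K, V = V, W = W)
    concat[, ((i - 1) * dk + 1):(i * dk)] <- O
  }
  list(y = concat %*% p$Wo, heads = heads, concat = concat)
}

mha_bwd <- function(x, p, cache, dy) {
  h <- length(p$Wq)
  dk <- ncol(p$Wq[[1]])
  dWo <- crossprod(cache$concat, dy)
  dconcat <- dy %*% t(p$Wo)
  dx <- matrix(0, nrow(x), ncol(x))
  dWq <- dWk <- dWv <- vector("list", h)
  for (i in seq_len(h)) {
    hc <- cache$heads[[i]]
    dO <- dconcat[, ((i - 1) * dk + 1):(i * dk), drop = FALSE]
    g <- attn_bwd(hc$Q, hc$K, hc$V, hc$W, dO)
    dWq[[i]] <- crossprod(x, g$dQ)
    dWk[[i]] <- crossprod(x, g$dK)
    dWv[[i]] <- crossprod(x, g$dV)
    dx <- dx + g$dQ %*% t(p$Wq[[i]]) + g$dK %*% t(p$Wk[[i]]) + g$dV %*% t(p$Wv[[i]])
  }
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# ---- dropout --------------------------------------------------------------

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# ---- positional encoding --------------------------------------------------

#' Sinusoidal positional encoding
#'
#' Fixed sine/cosine position code added to the encoder input so frame order
#' is visible to the (otherwise permutation-equivariant) attention layers.
#'
#' @param n Sequence length.
#' @param dim Model dimension.
#' @return An n x dim matrix.
#' @export
positional_encoding <- function(n, dim) {
  pe <- matrix(0, n, dim)
  pos <- seq_len(n) - 1
  for (i in seq_len(ceiling(dim / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / dim)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= dim) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}
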