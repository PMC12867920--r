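# Output head (300 -> 128 -> 64 -> 1, sigmoid x 100) and the high-load
# weighted mean squared error.

#' Initialize output-head parameters
#'
#' @param in_dim Input feature dimension (default 300, the selected feature
#'   subset size).
#' @param hidden Hidden widths of the two ReLU layers (default
#'   `c(128, 64)`).
#' @param seed Seed for the initialization.
#' @return A list of class `head_params`.
#' @export
head_init <- function(in_dim = 300, hidden = c(128, 64), seed = 1) {
  with_seed(seed, {
    structure(list(l1 = linear_init(in_dim, hidden[1]),
                   l2 = linear_init(hidden[1], hidden[2]),
                   l3 = linear_init(hidden[2], 1L)),
              class = "head_params")
  })
}

#' Cognitive-load score head
#'
#' `100 * sigmoid(W3 relu(W2 relu(W1 x + b1) + b2) + b3)`: two ReLU layers
#' compress the selected features, and the sigmoid maps the scalar output
#' into the open interval (0, 100).
#'
#' @param x Feature vector (length `in_dim`) or n x in_dim matrix.
#' @param params A [head_init()] parameter list.
#' @return Score(s) in `(0, 100)`.
#' @export
score_head <- function(x, params) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stop_if(ncol(x) != nrow(params$l1$W), "feature dimension mismatch")
  drop(head_fwd(x, params)$score)
}

head_fwd <- function(x, p) {
  z1 <- linear_fwd(x, p$l1); h1 <- relu(z1)
  z2 <- linear_fwd(h1, p$l2); h2 <- relu(z2)
  z3 <- linear_fwd(h2, p$l3)
  s <- sigmoid(z3)
  list(score = 100 * s, x = x, z1 = z1, h1 = h1, z2 = z2, h2 = h2, s = s)
}

head_bwd <- function(p, cache, dscore) {
  dz3 <- dscore * 100 * cache$s * (1 - cache$s)
  g3 <- linear_bwd(cache$h2, p$l3, dz3)
  dz2 <- g3$dx * (cache$z2 > 0)
  g2 <- linear_bwd(cache$h1, p$l2, dz2)
  dz1 <- g2$dx * (cache$z1 > 0)
  g1 <- linear_bwd(cache$x, p$l1, dz1)
  list(grads = list(l1 = list(W = g1$dW, b = g1$db),
                    l2 = list(W = g2$dW, b = g2$db),
                    l3 = list(W = g3$dW, b = g3$db)),
       dx = g1$dx)
}

#' High-load weighted mean squared error
#'
#' `sum_i w_i (yhat_i - y_i)^2` with `w_i = 1.5` when the true label
#' `y_i >= 70` (the high-load threshold, boundary included) and `w_i = 1`
#' otherwise, so errors on high-load movements are penalized more heavily.
#' The default reduction divides by the number of samples for batch-size
#' invariance; `reduction = "sum"` gives the literal sum.
#'
#' @param pred Predicted scores.
#' @param truth True labels on the `[0, 100]` scale.
#' @param threshold High-load threshold (default 70).
#' @param high_weight Weight for high-load samples (default 1.5).
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return The loss value.
#' @export
weighted_mse <- function(pred, truth, threshold = 70, high_weight = 1.5,
                         reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  stop_if(length(pred) == 0L, "empty input")
  stop_if(length(pred) != length(truth), "pred and truth must have equal length")
  w <- ifelse(truth >= threshold, high_weight, 1)
  total <- sum(w * (pred - truth)^2)
  if (reduction == "mean") total / length(pred) else total
}

# d loss / d pred for the mean reduction (used by the trainer).
weighted_mse_grad <- function(pred, truth, threshold = 70, high_weight = 1.5) {
  w <- ifelse(truth >= threshold, high_weight, 1)
  2 * w * (pred - truth) / length(pred)
}
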