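# Full model assembly: branch streams -> TCN -> attention encoder -> pooled
# global features -> feature mask -> score head.

#' Assemble the full cognitive-load model
#'
#' Wires the three-branch TCN, the attention encoder and the score head into
#' one trainable assembly. The pooled encoder output is gated by
#' `feature_idx` — the 300 indices chosen by the whale-optimization dual
#' search when available; without a search the first
#' `min(300, model_dim)` slots are used (documented default).
#'
#' @param tcn_cfg A [tcn_config()].
#' @param enc_cfg An [encoder_config()]; its `input_dim` must equal the TCN
#'   `out_dim`.
#' @param feature_idx 1-based indices into the pooled encoder features to
#'   feed the head; `NULL` for the default.
#' @param head_hidden Hidden widths of the head (default `c(128, 64)`).
#' @param seed Seed for all weight initializations.
#' @return A list of class `cogload_model` with `tcn`, `enc`, `head` parameter
#'   blocks and the `feature_idx`.
#' @export
cogload_model <- function(tcn_cfg = tcn_config(), enc_cfg = encoder_config(),
                          feature_idx = NULL, head_hidden = c(128, 64),
                          seed = 1) {
  stop_if(enc_cfg$input_dim != tcn_cfg$out_dim,
          "encoder input_dim must equal TCN out_dim")
  if (is.null(feature_idx)) {
    feature_idx <- seq_len(min(300L, enc_cfg$model_dim))
  }
  stop_if(any(feature_idx < 1 | feature_idx > enc_cfg$model_dim),
          "feature_idx out of range")
  seeds <- derive_seeds(seed, 3L)
  structure(list(tcn = tcn_init(tcn_cfg, seed = seeds[1]),
                 enc = encoder_init(enc_cfg, seed = seeds[2]),
                 head = head_init(length(feature_idx), head_hidden, seed = seeds[3]),
                 feature_idx = as.integer(feature_idx)),
            class = "cogload_model")
}

# Forward pass for one sequence's branch features; returns the score and the
# caches needed for the backward pass.
model_fwd <- function(model, branches, training = FALSE) {
  tc <- tcn_fwd(model$tcn, branches)
  ec <- enc_fwd(model$enc, tc$local, training)
  feats <- ec$pooled[model$feature_idx]
  hc <- head_fwd(matrix(feats, nrow = 1), model$head)
  list(score = drop(hc$score), tc = tc, ec = ec, hc = hc)
}

# Backward pass from d loss / d score; grads mirror the model structure.
model_bwd <- function(model, cache, dscore) {
  hb <- head_bwd(model$head, cache$hc, matrix(dscore, 1, 1))
  dpooled <- rep(0, model$enc$cfg$model_dim)
  dpooled[model$feature_idx] <- drop(hb$dx)
  eb <- enc_bwd(model$enc, cache$ec, dpooled = dpooled)
  tb <- tcn_bwd(model$tcn, cache$tc, eb$dx_in)
  list(tcn = tb, enc = list(lift = eb$lift, layers = eb$layers),
       head = hb$grads)
}

#' Predict cognitive-load scores for pose sequences
#'
#' Runs the full model (deterministically, dropout off) on each sequence's
#' branch features.
#'
#' @param model A [cogload_model()].
#' @param inputs List of [branch_features()] objects, or a list of
#'   [pose_sequence()] objects (branch features are computed on the fly).
#' @param topo Skeleton topology used when `inputs` are raw sequences.
#' @return Numeric vector of scores in `(0, 100)`.
#' @export
predict_load <- function(model, inputs, topo = default_skeleton()) {
  vapply(inputs, function(x) {
    if (inherits(x, "pose_sequence")) x <- branch_features(x, topo)
    model_fwd(model, x, training = FALSE)$score
  }, numeric(1))
}

# ---- generic parameter-tree utilities (used by the optimizer) -------------

# Apply f to every numeric leaf of a nested parameter list.
nn_map <- function(x, f) {
  if (is.list(x)) {
    keep <- !(names(x) %in% c("cfg", "feature_idx", "eps"))
    if (is.null(names(x))) keep <- rep(TRUE, length(x))
    x[keep] <- lapply(x[keep], nn_map, f = f)
    x
  } else if (is.numeric(x)) {
    f(x)
  } else {
    x
  }
}

# Apply f elementwise to the matching numeric leaves of two parameter trees.
# Matching is by name where names exist (the second tree may omit non-trained
# fields such as `cfg`), positional otherwise.
nn_map2 <- function(x, y, f) {
  if (is.list(x)) {
    keep <- !(names(x) %in% c("cfg", "feature_idx", "eps"))
    if (is.null(names(x))) keep <- rep(TRUE, length(x))
    for (i in which(keep)) {
      nm <- names(x)[i]
      yy <- if (!is.null(nm) && nzchar(nm)) y[[nm]] else y[[i]]
      if (is.null(yy)) next  # no counterpart (untrained field): leave as is
      x[[i]] <- nn_map2(x[[i]], yy, f)
    }
    x
  } else if (is.numeric(x)) {
    f(x, y)
  } else {
    x
  }
}

# Sum of f over numeric leaves (diagnostics).
nn_reduce <- function(x, f, acc = 0) {
  if (is.list(x)) {
    keep <- !(names(x) %in% c("cfg", "feature_idx"))
    if (is.null(names(x))) keep <- rep(TRUE, length(x))
    for (i in which(keep)) acc <- nn_reduce(x[[i]], f, acc)
    acc
  } else if (is.numeric(x)) {
    acc + f(x)
  } else {
    acc
  }
}
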